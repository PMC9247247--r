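#' @import tibble
#' @importFrom dplyr bind_rows arrange group_by ungroup summarise mutate filter
#'   select left_join n desc row_number
#' @importFrom methods as is
#' @importFrom stats rbinom rgeom runif setNames median chisq.test
#' @importFrom utils head tail write.table read.table
NULL

# Codon table kept as a plain named vector: translation of short segments is a
# hot path (functionality calls, leader enumeration) and building Biostrings
# objects per call dominates run time at these lengths.
.GENETIC_CODE <- Biostrings::GENETIC_CODE

.SENSE_CODONS <- names(.GENETIC_CODE)[.GENETIC_CODE != "*"]
.STOP_CODONS  <- names(.GENETIC_CODE)[.GENETIC_CODE == "*"]

#' Reverse complement of character vectors
#'
#' Thin wrapper over [Biostrings::reverseComplement()] keeping everything in
#' plain character space, which is how sequences travel through the pipeline.
#'
#' @param x character vector of DNA sequences (A/C/G/T/N).
#' @return character vector of the same length.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Translate a nucleotide sequence
#'
#' Translates in the frame starting at position 1; trailing bases that do not
#' fill a codon are ignored. Codons containing N translate to `X`.
#'
#' @param x single nucleotide string.
#' @return single amino-acid string (may contain `*`).
#' @export
translate_nt <- function(x) {
  stopifnot(length(x) == 1L)
  n <- nchar(x)
  if (n < 3L) return("")
  x <- substr(x, 1L, 3L * (n %/% 3L))
  codons <- substring(x, seq(1L, nchar(x), 3L), seq(3L, nchar(x), 3L))
  aa <- .GENETIC_CODE[codons]
  aa[is.na(aa)] <- "X"
  paste(aa, collapse = "")
}

#' @rdname translate_nt
#' @export
has_internal_stop <- function(x) {
  aa <- translate_nt(x)
  grepl("*", substr(aa, 1L, max(0L, nchar(aa) - 1L)), fixed = TRUE)
}

# IUPAC code -> regex character class (used for primer matching).
.IUPAC_REGEX <- c(
  A = "A", C = "C", G = "G", T = "T",
  R = "[AG]", Y = "[CT]", S = "[CG]", W = "[AT]", K = "[GT]", M = "[AC]",
  B = "[CGT]", D = "[AGT]", H = "[ACT]", V = "[ACG]", N = "[ACGT]"
)

# Expanded base sets per IUPAC code, for mismatch counting.
.IUPAC_SET <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

#' Count mismatches of reads against an IUPAC-ambiguous primer prefix
#'
#' Compares the first `nchar(primer)` bases of each read against the primer,
#' honouring IUPAC ambiguity codes in the primer (a read base matching any
#' base of the code is not a mismatch). Reads shorter than the primer get
#' `NA`.
#'
#' @param reads character vector of read sequences.
#' @param primer single primer string (IUPAC codes allowed).
#' @return integer vector of mismatch counts.
#' @export
iupac_prefix_mismatch <- function(reads, primer) {
  pl <- nchar(primer)
  ok <- nchar(reads) >= pl
  out <- rep(NA_integer_, length(reads))
  if (!any(ok)) return(out)
  sel <- reads[ok]
  pc <- strsplit(toupper(primer), "", fixed = TRUE)[[1]]
  mm <- integer(length(sel))
  for (i in seq_len(pl)) {
    allowed <- .IUPAC_SET[[pc[i]]]
    if (is.null(allowed)) allowed <- pc[i]
    mm <- mm + !(substr(sel, i, i) %in% allowed)
  }
  out[ok] <- mm
  out
}

.aa_submat <- local({
  letters <- strsplit("ARNDCQEGHILKMFPSTWYVBJZX*-+.", "")[[1]]
  m <- matrix(-1, length(letters), length(letters),
              dimnames = list(letters, letters))
  diag(m) <- 1
  m
})

.nt_submat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1)

#' Pairwise percent identity from a global alignment with free end gaps
#'
#' Globally aligns two sequences (match +1, mismatch -1, gap open -4, gap
#' extend -1, end gaps free) and returns identical positions divided by
#' aligned columns, end-gap overhang excluded. Free end gaps make the measure
#' meaningful for fragment-versus-gene comparisons. Symmetric in its
#' arguments.
#'
#' @param a,b sequences (single strings).
#' @param level `"nt"` or `"aa"`.
#' @return fraction in `[0, 1]`.
#' @export
pairwise_identity <- function(a, b, level = c("nt", "aa")) {
  level <- match.arg(level)
  if (!nzchar(a) || !nzchar(b)) {
    stop("pairwise_identity: empty input sequence")
  }
  # canonical argument order: alignment tie-breaking is role-dependent, so
  # fixing the roles makes the measure exactly symmetric
  if (a > b) { tmp <- a; a <- b; b <- tmp }
  if (level == "nt") {
    al <- Biostrings::pairwiseAlignment(
      Biostrings::DNAString(a), Biostrings::DNAString(b),
      type = "overlap", substitutionMatrix = .nt_submat,
      gapOpening = 4, gapExtension = 1
    )
  } else {
    al <- Biostrings::pairwiseAlignment(
      Biostrings::AAString(a), Biostrings::AAString(b),
      type = "overlap", substitutionMatrix = .aa_submat,
      gapOpening = 4, gapExtension = 1
    )
  }
  unname(Biostrings::pid(al, type = "PID1") / 100)
}

# Vectorised strict global nt identity (matches / alignment columns, end
# gaps included) of many patterns against one subject. The subgroup rule is
# a whole-gene criterion, so end gaps are not free here: a locally similar
# core must not pull two diverged genes into one subgroup.
.identity_many <- function(patterns, subject) {
  if (length(patterns) == 0L) return(numeric(0))
  al <- Biostrings::pairwiseAlignment(
    Biostrings::DNAStringSet(patterns), Biostrings::DNAString(subject),
    type = "global", substitutionMatrix = .nt_submat,
    gapOpening = 4, gapExtension = 1
  )
  as.numeric(Biostrings::pid(al, type = "PID1") / 100)
}

#' @rdname pairwise_identity
#' @details `global_identity()` is the whole-gene variant used for subgroup
#'   clustering: the same scoring but with end gaps penalized, so identity
#'   is evaluated over the full gene length.
#' @export
global_identity <- function(a, b) {
  if (!nzchar(a) || !nzchar(b)) stop("global_identity: empty input sequence")
  .identity_many(a, b)
}

# 0-based half-open interval on the forward strand <-> coordinates of the
# same interval seen on the reverse-complemented contig of length L.
.rc_interval <- function(start0, end0, L) {
  c(L - end0, L - start0)
}

# Longest exact common prefix length of two strings.
.common_prefix <- function(a, b) {
  n <- min(nchar(a), nchar(b))
  if (n == 0L) return(0L)
  av <- utf8ToInt(substr(a, 1L, n))
  bv <- utf8ToInt(substr(b, 1L, n))
  d <- which(av != bv)
  if (length(d) == 0L) n else d[1L] - 1L
}

# Longest exact common suffix length of two strings.
.common_suffix <- function(a, b) {
  n <- min(nchar(a), nchar(b))
  if (n == 0L) return(0L)
  av <- rev(utf8ToInt(a))[seq_len(n)]
  bv <- rev(utf8ToInt(b))[seq_len(n)]
  d <- which(av != bv)
  if (length(d) == 0L) n else d[1L] - 1L
}

# Longest common contiguous substring of `x` found anywhere in `core`;
# ties resolved towards the leftmost position in `x`, then in `core`.
# Returns list(len, x_start, core_start) with 1-based starts, len 0 if none.
.longest_core_match <- function(x, core) {
  nx <- nchar(x); nc <- nchar(core)
  best <- list(len = 0L, x_start = 0L, core_start = 0L)
  if (nx == 0L || nc == 0L) return(best)
  for (i in seq_len(nx)) {
    if (nx - i + 1L <= best$len) break
    for (j in seq_len(nc)) {
      l <- 0L
      while (i + l <= nx && j + l <= nc &&
             substr(x, i + l, i + l) == substr(core, j + l, j + l)) {
        l <- l + 1L
      }
      if (l > best$len) best <- list(len = l, x_start = i, core_start = j)
    }
  }
  best
}

#' Read a seed FASTA with typed headers
#'
#' Seed headers carry whitespace-separated `key=value` tokens after the id,
#' e.g. `>OnmyV3 type=V subgroup=3` or `>C09 type=C exon=2 gene=C09`.
#' Seeds without a `subgroup` token still drive candidate discovery but do
#' not anchor subgroup numbering.
#'
#' @param x path to a FASTA file or a named [Biostrings::DNAStringSet].
#' @return tibble with columns `seed_id`, `type`, `subgroup`, `gene`, `exon`,
#'   `seq`.
#' @export
read_seeds <- function(x) {
  if (is.character(x) && length(x) == 1L && file.exists(x)) {
    x <- Biostrings::readDNAStringSet(x)
  }
  stopifnot(is(x, "DNAStringSet"))
  if (length(x) == 0L) stop("read_seeds: empty seed set")
  hdr <- names(x)
  tok1 <- sub("\\s.*$", "", hdr)
  get_tok <- function(key) {
    m <- regmatches(hdr, regexpr(paste0(key, "=[^ ]+"), hdr))
    out <- rep(NA_character_, length(hdr))
    hit <- grepl(paste0(key, "="), hdr)
    out[hit] <- sub(paste0("^.*", key, "="), "",
                    regmatches(hdr, regexpr(paste0(key, "=[^ ]+"), hdr)))
    out
  }
  tibble(
    seed_id  = tok1,
    type     = toupper(get_tok("type")),
    subgroup = suppressWarnings(as.integer(get_tok("subgroup"))),
    gene     = get_tok("gene"),
    exon     = suppressWarnings(as.integer(get_tok("exon"))),
    seq      = as.character(x)
  )
}

#' Write a seed tibble as FASTA
#' @param seeds tibble as returned by [read_seeds()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_seeds <- function(seeds, path) {
  hdr <- paste0(seeds$seed_id, " type=", seeds$type)
  hdr <- ifelse(!is.na(seeds$subgroup),
                paste0(hdr, " subgroup=", seeds$subgroup), hdr)
  if ("gene" %in% names(seeds)) {
    hdr <- ifelse(!is.na(seeds$gene), paste0(hdr, " gene=", seeds$gene), hdr)
  }
  if ("exon" %in% names(seeds)) {
    hdr <- ifelse(!is.na(seeds$exon), paste0(hdr, " exon=", seeds$exon), hdr)
  }
  ss <- Biostrings::DNAStringSet(seeds$seq)
  names(ss) <- hdr
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}
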