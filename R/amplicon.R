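# ---------------------------------------------------------------------------
# Paired-end amplicon processing: quality trimming, primer demultiplexing
# (IUPAC-aware), overlap merging, collapsing to unique sequences with read
# support, ORF filtering anchored at the constant gene, germline assignment
# at 100% identity, and expressed-support marking.
# ---------------------------------------------------------------------------

#' Construct a primer set
#'
#' @param x tibble with columns `primer_id`, `direction` (`"fwd"`/`"rev"`),
#'   `gs` (gene-specific part, IUPAC codes allowed) and `tail` (adapter
#'   tail, not matched against reads).
#' @return object of class `trb_primer_set` with elements `fwd`, `rev`,
#'   `all`.
#' @export
primer_set <- function(x) {
  stopifnot(all(c("primer_id", "direction", "gs", "tail") %in% names(x)))
  if (any(!nzchar(x$gs))) stop("primer_set: empty gene-specific part")
  structure(list(fwd = x[x$direction == "fwd", , drop = FALSE],
                 rev = x[x$direction == "rev", , drop = FALSE],
                 all = x),
            class = "trb_primer_set")
}

#' Default TRB amplicon primer panel
#'
#' First-PCR primer sequences for twelve V-subgroup forward primers and the
#' two region-specific constant-gene reverse primers, with the Illumina
#' adapter tails separated from the gene-specific 3' parts (only the latter
#' are matched during demultiplexing). Several forward primers contain IUPAC
#' ambiguity codes (S, M).
#'
#' @return a [primer_set()].
#' @export
trb_primers <- function() {
  ftail <- "ACACTCTTTCCCTACACGACGCTCTTCCGATCT"
  rtail <- "GTGACTGGAGTTCAGACGTGTGCTCTTCCGATCT"
  fwd <- c(
    "V1.F"     = "GGTCTTGTTGAGGGGAGTGA",
    "V2.F"     = "CCAGGGAGAGTCGGCTAAGA",
    "V3.F"     = "AGTTCAACTSAMCTGCAGMC",
    "V4.F"     = "GCCTAATGCCTCTGTCACACT",
    "V5.F"     = "AGGTTCACCAGACTCCCTCT",
    "V7.F"     = "GTCTCCTGTCCTGTCTGTGTG",
    "V8.F"     = "GTTGCGTTTCGTCAGTCTCC",
    "V9.F"     = "GTTCCTGTGTGTCCCTCTCC",
    "V10.F1"   = "TGGGCAGTAAAGTCCTCCAG",
    "V10.F2"   = "TCCAGGTTCCCTCAGCACTA",
    "V11/13.F" = "TCAACTCACCTGCAGCCATACT",
    "V12.F"    = "ATCTCCGCTGTTCTCACACT"
  )
  rev <- c(
    "TRB01.R" = "GTTGTCGGTCCCAACTCCAT",
    "TRB09.R" = "GACTTGCCAGAAGACCGTGA"
  )
  primer_set(dplyr::bind_rows(
    tibble(primer_id = names(fwd), direction = "fwd", gs = unname(fwd), tail = ftail),
    tibble(primer_id = names(rev), direction = "rev", gs = unname(rev), tail = rtail)
  ))
}

#' Read paired FASTQ files
#'
#' @param r1,r2 FASTQ paths (mate 1 and mate 2, records in sync).
#' @return tibble `id`, `r1`, `q1`, `r2`, `q2`.
#' @export
read_fastq_pairs <- function(r1, r2) {
  s1 <- Biostrings::readDNAStringSet(r1, format = "fastq", with.qualities = TRUE)
  s2 <- Biostrings::readDNAStringSet(r2, format = "fastq", with.qualities = TRUE)
  id1 <- sub("\\s.*$", "", names(s1))
  id2 <- sub("\\s.*$", "", names(s2))
  if (length(s1) != length(s2) || any(id1 != id2)) {
    first <- if (length(s1) != length(s2)) min(length(s1), length(s2)) + 1L
             else which(id1 != id2)[1]
    stop("desynchronized FASTQ pair at record ", first, ": ",
         if (first <= length(s1)) id1[first] else "<missing>")
  }
  tibble(id = unname(id1),
         r1 = unname(as.character(s1)),
         q1 = unname(as.character(S4Vectors::mcols(s1)$qualities)),
         r2 = unname(as.character(s2)),
         q2 = unname(as.character(S4Vectors::mcols(s2)$qualities)))
}

#' Write paired FASTQ files
#' @param pairs tibble as from [read_fastq_pairs()].
#' @param prefix output prefix; writes `<prefix>_R1.fastq`, `<prefix>_R2.fastq`.
#' @return the two paths, invisibly.
#' @export
write_fastq_pairs <- function(pairs, prefix) {
  p1 <- paste0(prefix, "_R1.fastq"); p2 <- paste0(prefix, "_R2.fastq")
  s1 <- Biostrings::DNAStringSet(pairs$r1); names(s1) <- pairs$id
  s2 <- Biostrings::DNAStringSet(pairs$r2); names(s2) <- pairs$id
  Biostrings::writeXStringSet(s1, p1, format = "fastq",
                              qualities = Biostrings::BStringSet(pairs$q1))
  Biostrings::writeXStringSet(s2, p2, format = "fastq",
                              qualities = Biostrings::BStringSet(pairs$q2))
  invisible(c(p1, p2))
}

# Best insert-size hypothesis for a mate pair. `rc2` is revcomp(r2).
# Scans candidate insert lengths, counting mismatches over the implied
# overlap; returns list(ins, overlap, mismatch, density) or NULL.
# Candidates are visited longest-overlap-first so a perfect overlap (the
# common case for clean reads) short-circuits the scan: a zero-density hit
# cannot be beaten, and the tie-break prefers the longest overlap anyway.
.best_insert <- function(r1, rc2, q1 = NULL, q2rev = NULL,
                         min_overlap = 10L, max_density = 0.25) {
  l1 <- nchar(r1); l2 <- nchar(rc2)
  if (l1 == 0L || l2 == 0L) return(NULL)
  a <- utf8ToInt(r1)
  b <- utf8ToInt(rc2)
  # match counts for every shift at once via cross-correlation per base
  M <- 0
  for (L in utf8ToInt("ACGT")) {
    M <- M + stats::convolve(as.numeric(a == L), as.numeric(b == L),
                             type = "open")
  }
  M <- round(M)                       # shifts -(l2-1) .. (l1-1)
  ins_all <- seq.int(-(l2 - 1L), l1 - 1L) + l2
  ovs <- pmin(l1, ins_all) - pmax(1L, ins_all - l2 + 1L) + 1L
  mm <- ovs - M
  den <- mm / ovs
  ok <- which(ovs >= min_overlap & den <= max_density &
                ins_all >= min_overlap & ins_all <= l1 + l2 - min_overlap)
  if (length(ok) == 0L) return(NULL)
  ord <- ok[order(den[ok], -ovs[ok], ins_all[ok])]
  k <- ord[1]
  list(ins = ins_all[k], overlap = ovs[k], mismatch = mm[k], density = den[k])
}

#' Quality-trim and adapter-clean read pairs
#'
#' Trims trailing bases below the quality threshold from the 3' end of each
#' mate, removes adapter read-through by overlap (when the mates' overlap
#' implies an insert shorter than a read, both mates are cut back to the
#' insert), and drops pairs where either mate falls below the length floor.
#'
#' @param pairs read-pair tibble.
#' @param min_q Phred threshold for 3' trimming.
#' @param min_len minimum mate length after trimming.
#' @return filtered tibble; attribute `n_dropped` counts removed pairs.
#' @export
quality_trim <- function(pairs, min_q = 20L, min_len = 50L) {
  trim_one <- function(seq, qual) {
    q <- utf8ToInt(qual) - 33L
    keep <- which(q >= min_q)
    last <- if (length(keep)) max(keep) else 0L
    c(substr(seq, 1L, last), substr(qual, 1L, last))
  }
  n <- nrow(pairs)
  out <- pairs
  for (i in seq_len(n)) {
    t1 <- trim_one(out$r1[i], out$q1[i])
    t2 <- trim_one(out$r2[i], out$q2[i])
    out$r1[i] <- t1[1]; out$q1[i] <- t1[2]
    out$r2[i] <- t2[1]; out$q2[i] <- t2[2]
  }
  rc2_all <- if (n) revcomp(out$r2) else character(0)
  for (i in seq_len(n)) {
    l1 <- nchar(out$r1[i]); l2 <- nchar(out$r2[i])
    if (l1 >= min_len && l2 >= min_len) {
      bi <- .best_insert(out$r1[i], rc2_all[i],
                         min_overlap = 12L, max_density = 0.10)
      if (!is.null(bi) && bi$ins < max(l1, l2)) {
        k1 <- min(l1, bi$ins); k2 <- min(l2, bi$ins)
        out$r1[i] <- substr(out$r1[i], 1L, k1); out$q1[i] <- substr(out$q1[i], 1L, k1)
        out$r2[i] <- substr(out$r2[i], 1L, k2); out$q2[i] <- substr(out$q2[i], 1L, k2)
      }
    }
  }
  keep <- nchar(out$r1) >= min_len & nchar(out$r2) >= min_len
  res <- out[keep, , drop = FALSE]
  attr(res, "n_dropped") <- sum(!keep)
  res
}

#' Demultiplex read pairs by first-PCR primers
#'
#' A pair is binned to `(f, r)` iff mate 1 starts with forward primer `f`'s
#' gene-specific part and mate 2 with reverse primer `r`'s, each within
#' `max_mismatch` mismatches under IUPAC-aware matching. A read matching two
#' primers equally well is not guessed: the pair goes to `undetermined`.
#' Bins plus `undetermined` partition the input exactly.
#'
#' @param pairs read-pair tibble.
#' @param primers a [primer_set()].
#' @param max_mismatch allowed mismatches in the gene-specific part.
#' @return list with `bins` (named list of tibbles, names `"{f}|{r}"`) and
#'   `undetermined` (tibble).
#' @export
demultiplex <- function(pairs, primers, max_mismatch = 1L) {
  stopifnot(inherits(primers, "trb_primer_set"))
  if (nrow(primers$fwd) == 0L || nrow(primers$rev) == 0L) {
    stop("demultiplex: need at least one forward and one reverse primer")
  }
  if (nrow(pairs) == 0L) return(list(bins = list(), undetermined = pairs))
  pick <- function(reads, prim) {
    mm <- vapply(prim$gs, function(g) iupac_prefix_mismatch(reads, g),
                 integer(length(reads)))
    if (is.null(dim(mm))) mm <- matrix(mm, nrow = length(reads))
    big <- 1e9
    mm2 <- mm; mm2[is.na(mm2)] <- big
    mn <- do.call(pmin, as.data.frame(mm2))
    n_at_min <- rowSums(mm2 == mn)
    sel <- max.col(-mm2, ties.method = "first")
    sel[mn > max_mismatch | n_at_min != 1L] <- NA_integer_  # ambiguity is not guessed
    sel
  }
  f <- pick(pairs$r1, primers$fwd)
  r <- pick(pairs$r2, primers$rev)
  assigned <- !is.na(f) & !is.na(r)
  key <- rep(NA_character_, nrow(pairs))
  key[assigned] <- paste0(primers$fwd$primer_id[f[assigned]], "|",
                          primers$rev$primer_id[r[assigned]])
  bins <- lapply(split(which(assigned), key[assigned]),
                 function(ix) pairs[ix, , drop = FALSE])
  list(bins = bins, undetermined = pairs[!assigned, , drop = FALSE])
}

#' Merge read pairs by overlap
#'
#' Chooses the insert-size hypothesis with the lowest overlap mismatch
#' density (ties: longest overlap) subject to a minimum overlap and a
#' maximum density; disagreeing overlap bases are resolved towards the
#' higher-quality call (ties towards mate 1). Unmergeable pairs are dropped
#' and counted.
#'
#' @param pairs read-pair tibble.
#' @param min_overlap minimum overlap (nt).
#' @param max_mismatch_density maximum mismatch fraction in the overlap.
#' @return tibble `id`, `sequence`; attribute `n_unmerged`.
#' @export
merge_pairs <- function(pairs, min_overlap = 10L, max_mismatch_density = 0.25) {
  out_id <- character(nrow(pairs)); out_seq <- character(nrow(pairs))
  n_out <- 0L
  n_unmerged <- 0L
  rc2_all <- if (nrow(pairs)) revcomp(pairs$r2) else character(0)
  for (i in seq_len(nrow(pairs))) {
    r1 <- pairs$r1[i]; rc2 <- rc2_all[i]
    q1 <- utf8ToInt(pairs$q1[i]) - 33L
    q2 <- rev(utf8ToInt(pairs$q2[i]) - 33L)
    bi <- .best_insert(r1, rc2, min_overlap = min_overlap,
                       max_density = max_mismatch_density)
    if (is.null(bi)) { n_unmerged <- n_unmerged + 1L; next }
    ins <- bi$ins
    l1 <- nchar(r1); l2 <- nchar(rc2)
    a <- utf8ToInt(r1); b <- utf8ToInt(rc2)
    p <- seq_len(ins)
    p2 <- p - (ins - l2)
    in1 <- p <= l1
    in2 <- p2 >= 1L & p2 <= l2
    merged <- integer(ins)
    merged[in1] <- a[p[in1]]
    only2 <- !in1 & in2
    merged[only2] <- b[p2[only2]]
    both <- in1 & in2
    use2 <- both & (a[pmin(p, l1)] != b[pmax(p2, 1L)]) &
      (q1[pmin(p, l1)] < q2[pmax(p2, 1L)])
    merged[use2] <- b[p2[use2]]
    n_out <- n_out + 1L
    out_id[n_out] <- pairs$id[i]
    out_seq[n_out] <- intToUtf8(merged)
  }
  res <- tibble(id = out_id[seq_len(n_out)], sequence = out_seq[seq_len(n_out)])
  attr(res, "n_unmerged") <- n_unmerged
  res
}

#' Collapse merged sequences to unique fragments with read support
#'
#' Exact-sequence grouping; the sum of counts equals the input size. Output
#' is sorted by descending count, then lexicographic sequence, and ids
#' follow the `{primer}_{rank}-{count}` convention of collapsed amplicon
#' read names.
#'
#' @param sequences character vector of merged sequences.
#' @param primer_pair label used in sequence ids (e.g. `"V9"`).
#' @return tibble `sequence_id`, `sequence`, `count`, `rank`, `primer_pair`.
#' @export
collapse_reads <- function(sequences, primer_pair = "amplicon") {
  if (length(sequences) == 0L) {
    return(tibble(sequence_id = character(0), sequence = character(0),
                  count = integer(0), rank = integer(0),
                  primer_pair = character(0)))
  }
  tab <- table(sequences)
  res <- tibble(sequence = names(tab), count = as.integer(tab))
  res <- res[order(-res$count, res$sequence), , drop = FALSE]
  res$rank <- seq_len(nrow(res))
  res$primer_pair <- primer_pair
  res$sequence_id <- sprintf("%s_%d-%d", primer_pair, res$rank, res$count)
  res[, c("sequence_id", "sequence", "count", "rank", "primer_pair")]
}

# Locate constant-gene anchors in a sequence: returns tibble(region, pos)
# of regions whose C-gene prefix (first `anchor` nt) occurs in the read.
.find_c_anchor <- function(sequence, c_refs, anchor = 30L) {
  hits <- list()
  for (r in names(c_refs)) {
    pat <- substr(c_refs[[r]], 1L, anchor)
    p <- regexpr(pat, sequence, fixed = TRUE)
    if (p > 0L) hits[[length(hits) + 1L]] <- tibble(region = r, pos = as.integer(p))
  }
  dplyr::bind_rows(hits)
}

#' Flag open-reading-frame amplicons
#'
#' Anchors the reading frame at the constant-gene suffix of each collapsed
#' sequence and flags it `orf_ok` when the anchored frame is stop-free from
#' the 5' end through the constant suffix. Sequences without a recognizable
#' constant anchor are flagged `FALSE` with the reason recorded.
#'
#' @param collapsed tibble from [collapse_reads()].
#' @param c_refs named character vector: region label -> constant-gene
#'   nucleotide sequence (spliced).
#' @param anchor length of the constant-gene prefix used as anchor.
#' @return `collapsed` with columns `orf_ok`, `orf_reason`, `c_pos`.
#' @export
orf_filter <- function(collapsed, c_refs, anchor = 30L) {
  n <- nrow(collapsed)
  collapsed$orf_ok <- FALSE
  collapsed$orf_reason <- NA_character_
  collapsed$c_pos <- NA_integer_
  for (i in seq_len(n)) {
    hits <- .find_c_anchor(collapsed$sequence[i], c_refs, anchor)
    if (nrow(hits) == 0L) { collapsed$orf_reason[i] <- "no_c_anchor"; next }
    cp <- hits$pos[1]
    collapsed$c_pos[i] <- cp
    off <- (cp - 1L) %% 3L
    aa <- translate_nt(substr(collapsed$sequence[i], off + 1L,
                              nchar(collapsed$sequence[i])))
    if (grepl("*", aa, fixed = TRUE)) {
      collapsed$orf_reason[i] <- "internal_stop"
    } else {
      collapsed$orf_ok[i] <- TRUE
    }
  }
  collapsed
}

#' Assign germline V and C genes at 100% identity
#'
#' A collapsed sequence's `v_call` is the set of all germline V genes whose
#' covered portion (from the end of the primer-binding prefix to the V-gene
#' 3' end, minus at most `max_v_trim` junction-trimmed bases) matches the
#' read exactly; sequence-identical germline genes yield multi-member
#' ambiguity sets that are never silently resolved. Sequences matching no V
#' are flagged `novel`. The `c_call` is the region whose constant-gene
#' anchor occurs in the read; a read anchoring both regions signals a
#' pipeline bug and is an error.
#'
#' @param collapsed tibble from [orf_filter()] (or [collapse_reads()]).
#' @param annotation a `trb_annotation`.
#' @param primer_skip length of the primer-binding prefix excluded from the
#'   identity evaluation.
#' @param max_v_trim maximum 3' V trimming tolerated while still calling
#'   the gene fully covered.
#' @param anchor constant-anchor length.
#' @return tibble: `sequence_id`, `sequence`, `count`, `orf_ok`, `v_call`
#'   (comma-joined names), `v_call_list`, `novel`, `c_call`, `c_pos`.
#' @export
assign_germline <- function(collapsed, annotation, primer_skip = 20L,
                            max_v_trim = 15L, anchor = 30L) {
  segs <- annotation$segments
  vt <- segs[segs$segment_type == "V", , drop = FALSE]
  if (nrow(vt) == 0L || all(is.na(vt$name))) {
    stop("assign_germline: annotation must be named")
  }
  c_refs <- setNames(
    segs$nt[segs$segment_type == "C" & segs$unit == "fwd"],
    segs$region_label[segs$segment_type == "C" & segs$unit == "fwd"])
  c_refs <- c_refs[!duplicated(names(c_refs))]
  out <- collapsed
  out$v_call <- NA_character_
  out$v_call_list <- vector("list", nrow(out))
  out$novel <- FALSE
  out$c_call <- NA_character_
  if (!"c_pos" %in% names(out)) out$c_pos <- NA_integer_
  v_body <- substr(vt$nt, primer_skip + 1L, nchar(vt$nt))
  v_need <- nchar(v_body) - max_v_trim
  for (i in seq_len(nrow(out))) {
    sq <- out$sequence[i]
    body <- substr(sq, primer_skip + 1L, nchar(sq))
    m <- vapply(v_body, function(v) .common_prefix(body, v), integer(1))
    calls <- which(m >= pmax(v_need, 1L))
    if (length(calls) == 0L) {
      out$novel[i] <- TRUE
    } else {
      nm <- sort(vt$name[calls])
      out$v_call[i] <- paste(nm, collapse = ",")
      out$v_call_list[[i]] <- nm
    }
    hits <- .find_c_anchor(sq, c_refs, anchor)
    if (nrow(hits) > 1L) {
      stop("assign_germline: sequence ", out$sequence_id[i],
           " matches the constant anchor of multiple regions (",
           paste(hits$region, collapse = ", "),
           "); paralogous regions are divergent, so this signals a pipeline bug")
    }
    if (nrow(hits) == 1L) {
      out$c_call[i] <- hits$region[1]
      if (is.na(out$c_pos[i])) out$c_pos[i] <- hits$pos[1]
    }
  }
  out
}

#' Mark germline V genes with expressed support
#'
#' A germline V gene gains functionality `F` when some open-reading-frame
#' collapsed sequence supported by at least `min_support` reads includes it
#' in its `v_call` ambiguity set. Pseudogenes matched by bona fide
#' transcripts keep their `P` label and are reported as status conflicts
#' (genomic sequencing error or haplotypic variation in pseudogene status).
#'
#' @param annotation a `trb_annotation`.
#' @param clonotypes tibble from [assign_germline()].
#' @param min_support read-support threshold.
#' @return list: `annotation` (updated), `conflicts` (tibble of P genes
#'   with expressed support).
#' @export
mark_expressed <- function(annotation, clonotypes, min_support = 20L) {
  segs <- annotation$segments
  ok <- clonotypes$orf_ok & !clonotypes$novel & clonotypes$count >= min_support
  supported <- unique(unlist(clonotypes$v_call_list[ok]))
  conflicts <- list()
  for (nm in supported) {
    i <- which(segs$name == nm)
    if (length(i) != 1L) next
    if (segs$functionality[i] == "P") {
      conflicts[[length(conflicts) + 1L]] <- tibble(
        name = nm, region = segs$region_label[i],
        note = "pseudogene with bona fide expressed support")
    } else {
      segs$functionality[i] <- "F"
    }
  }
  annotation$segments <- segs
  list(annotation = annotation, conflicts = dplyr::bind_rows(conflicts))
}
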