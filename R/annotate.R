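# ---------------------------------------------------------------------------
# Germline V/D/J/C mining and classification.
#
# Candidate discovery is a k-mer seeded, banded alignment against a typed
# seed library (11-mer seeding for V/J/C, exact scan for the short D core),
# followed by subgroup clustering at the 75% nucleotide-identity rule,
# functionality calling on internal stop codons, leader-exon recovery and
# the two-orientation naming scheme.
# ---------------------------------------------------------------------------

.as_genome <- function(genome) {
  if (is(genome, "DNAStringSet")) genome <- setNames(as.character(genome), names(genome))
  if (is.character(genome) && length(genome) == 1L && file.exists(genome)) {
    genome <- setNames(as.character(Biostrings::readDNAStringSet(genome)),
                       names(Biostrings::readDNAStringSet(genome)))
  }
  if (!is.character(genome) || length(genome) == 0L || is.null(names(genome))) {
    stop("genome must be a non-empty named character vector, DNAStringSet or FASTA path")
  }
  names(genome) <- sub("\\s.*$", "", names(genome))
  genome
}

# k-mer hit diagonals of `seed` against `subject`; returns candidate 1-based
# genomic start positions with their k-mer support.
.kmer_diagonals <- function(seed, subject, k = 11L) {
  L <- nchar(seed)
  if (L < k) return(tibble(diag = integer(0), support = integer(0)))
  kstarts <- seq_len(L - k + 1L)
  kms <- substring(seed, kstarts, kstarts + k - 1L)
  keep <- !grepl("[^ACGT]", kms)
  kms <- kms[keep]; kstarts <- kstarts[keep]
  if (length(kms) == 0L) return(tibble(diag = integer(0), support = integer(0)))
  pd <- Biostrings::PDict(kms)
  mi <- Biostrings::matchPDict(pd, subject)
  cnt <- S4Vectors::elementNROWS(mi)
  if (sum(cnt) == 0L) return(tibble(diag = integer(0), support = integer(0)))
  pat <- rep(seq_along(cnt), cnt)
  pos <- unlist(Biostrings::startIndex(mi), use.names = FALSE)
  diag <- pos - kstarts[pat] + 1L
  # cluster nearby diagonals (substitution-only model: one diagonal per gene)
  d <- sort(unique(diag))
  grp <- cumsum(c(TRUE, diff(d) > 8L))
  tab <- tabulate(match(diag, d))
  support <- vapply(split(tab, grp), sum, numeric(1))
  start <- vapply(split(d, grp), min, numeric(1))
  tibble(diag = as.integer(start), support = as.integer(support))
}

#' Mine a genome for TRB segment candidates
#'
#' Searches both strands of each contig for matches to a typed seed library.
#' V, J and C seeds are located by 11-mer seeding followed by banded global
#' alignment of the full seed into the candidate window; D seeds (short
#' cores, <= 20 nt) by exact scan. Overlapping hits of the same type are
#' merged to the best-scoring interval, and per-exon constant-gene hits are
#' chained into multi-exon segments.
#'
#' @param genome named character vector of contigs, `DNAStringSet`, or a
#'   FASTA path.
#' @param seeds seed tibble from [read_seeds()], a `DNAStringSet` with typed
#'   headers, or a FASTA path.
#' @param min_identity minimum alignment identity for V/C hits.
#' @param min_coverage minimum fraction of the seed that must align.
#' @param j_min_identity minimum identity for J hits (short seeds need a
#'   stricter rule).
#' @param k k-mer length for seeding.
#' @param min_kmer_hits minimum diagonal support to trigger an alignment.
#' @return tibble of candidate segments: `contig`, `segment_type`, `strand`,
#'   `start`, `end` (0-based half-open, forward strand), `exon_starts`,
#'   `exon_ends` (list columns), `nt` (spliced, coding strand), `seed_id`,
#'   `seed_subgroup`, `identity`, `coverage`, `score`.
#' @export
find_candidates <- function(genome, seeds, min_identity = 0.70,
                            min_coverage = 0.60, j_min_identity = 0.80,
                            k = 11L, min_kmer_hits = 2L) {
  genome <- .as_genome(genome)
  if (is.character(seeds) || is(seeds, "DNAStringSet")) seeds <- read_seeds(seeds)
  if (nrow(seeds) == 0L) stop("find_candidates: empty seed set")
  if (min_identity <= 0 || min_identity > 1) stop("min_identity must be in (0,1]")
  missing_types <- setdiff(c("V", "D", "J", "C"), unique(seeds$type))
  if (length(missing_types) > 0L) {
    warning("no seeds for segment type(s): ", paste(missing_types, collapse = ", "),
            "; those types will be absent from the output")
  }

  rows <- list()
  for (ci in seq_along(genome)) {
    contig <- names(genome)[ci]
    Lc <- nchar(genome[[ci]])
    for (strand in c("+", "-")) {
      scanned_chr <- if (strand == "+") genome[[ci]] else revcomp(genome[[ci]])
      scanned <- Biostrings::DNAString(scanned_chr)
      for (si in seq_len(nrow(seeds))) {
        sd <- seeds[si, ]
        if (sd$type == "D" || nchar(sd$seq) <= 20L) {
          m <- Biostrings::matchPattern(sd$seq, scanned)
          for (h in seq_along(m)) {
            s1 <- BiocGenerics::start(m)[h]; e1 <- BiocGenerics::end(m)[h]
            iv <- if (strand == "+") c(s1 - 1L, e1) else .rc_interval(s1 - 1L, e1, Lc)
            rows[[length(rows) + 1L]] <- tibble(
              contig = contig, segment_type = sd$type, strand = strand,
              start = iv[1], end = iv[2],
              exon_starts = list(iv[1]), exon_ends = list(iv[2]),
              nt = sd$seq, seed_id = sd$seed_id,
              seed_subgroup = sd$subgroup, seed_gene = sd$gene,
              seed_exon = sd$exon, identity = 1, coverage = 1,
              score = nchar(sd$seq))
          }
          next
        }
        dg <- .kmer_diagonals(sd$seq, scanned, k = k)
        dg <- dg[dg$support >= min_kmer_hits, , drop = FALSE]
        L <- nchar(sd$seq)
        for (h in seq_len(nrow(dg))) {
          ws <- max(1L, dg$diag[h] - 30L)
          we <- min(Lc, dg$diag[h] + L + 30L)
          window <- substr(scanned_chr, ws, we)
          al <- Biostrings::pairwiseAlignment(
            Biostrings::DNAString(sd$seq), Biostrings::DNAString(window),
            type = "global-local", substitutionMatrix = .nt_submat,
            gapOpening = 4, gapExtension = 1)
          ident <- unname(Biostrings::pid(al, type = "PID1") / 100)
          pat <- Biostrings::pattern(al)
          cov <- (BiocGenerics::end(pat) - BiocGenerics::start(pat) + 1L) / L
          thr <- if (sd$type == "J") j_min_identity else min_identity
          if (ident < thr || cov < min_coverage) next
          s1 <- ws + BiocGenerics::start(Biostrings::subject(al)) - 1L
          e1 <- ws + BiocGenerics::end(Biostrings::subject(al)) - 1L
          iv <- if (strand == "+") c(s1 - 1L, e1) else .rc_interval(s1 - 1L, e1, Lc)
          rows[[length(rows) + 1L]] <- tibble(
            contig = contig, segment_type = sd$type, strand = strand,
            start = iv[1], end = iv[2],
            exon_starts = list(iv[1]), exon_ends = list(iv[2]),
            nt = substr(scanned_chr, s1, e1), seed_id = sd$seed_id,
            seed_subgroup = sd$subgroup, seed_gene = sd$gene,
            seed_exon = sd$exon, identity = ident, coverage = cov,
            score = as.numeric(Biostrings::score(al)))
        }
      }
    }
  }
  if (length(rows) == 0L) {
    return(tibble(contig = character(0), segment_type = character(0),
                  strand = character(0), start = integer(0), end = integer(0),
                  exon_starts = list(), exon_ends = list(), nt = character(0),
                  seed_id = character(0), seed_subgroup = integer(0),
                  identity = numeric(0), coverage = numeric(0),
                  score = numeric(0)))
  }
  hits <- dplyr::bind_rows(rows)

  # merge overlapping hits of the same type: keep the best-scoring interval
  merge_overlaps <- function(h) {
    h <- h[order(-h$score, h$contig, h$start), , drop = FALSE]
    keep <- rep(TRUE, nrow(h))
    for (i in seq_len(nrow(h))) {
      if (!keep[i]) next
      j <- which(keep & seq_len(nrow(h)) > i &
                   h$contig == h$contig[i] & h$strand == h$strand[i] &
                   h$start < h$end[i] & h$end > h$start[i])
      keep[j] <- FALSE
    }
    h[keep, , drop = FALSE]
  }
  merged <- dplyr::bind_rows(lapply(split(hits, hits$segment_type), merge_overlaps))

  # chain per-exon constant-gene hits into multi-exon segments
  c_hits <- merged[merged$segment_type == "C", , drop = FALSE]
  other <- merged[merged$segment_type != "C", , drop = FALSE]
  c_rows <- list()
  if (nrow(c_hits) > 0L) {
    key <- paste(c_hits$contig, c_hits$strand, c_hits$seed_gene)
    for (grp in split(seq_len(nrow(c_hits)), key)) {
      h <- c_hits[grp, , drop = FALSE]
      h <- h[order(h$start), , drop = FALSE]
      cl <- cumsum(c(TRUE, diff(h$start) > 2000L))
      for (cc in split(seq_len(nrow(h)), cl)) {
        g <- h[cc, , drop = FALSE]
        contig_seq <- genome[[g$contig[1]]]
        ex <- g[order(g$start), c("start", "end")]
        pieces <- substring(contig_seq, ex$start + 1L, ex$end)
        nt <- if (g$strand[1] == "+") paste(pieces, collapse = "")
              else paste(rev(vapply(pieces, revcomp, character(1))), collapse = "")
        c_rows[[length(c_rows) + 1L]] <- tibble(
          contig = g$contig[1], segment_type = "C", strand = g$strand[1],
          start = min(g$start), end = max(g$end),
          exon_starts = list(ex$start), exon_ends = list(ex$end),
          nt = nt, seed_id = g$seed_id[1],
          seed_subgroup = NA_integer_, seed_gene = g$seed_gene[1],
          seed_exon = NA_integer_,
          identity = sum(g$identity * (g$end - g$start)) / sum(g$end - g$start),
          coverage = 1, score = sum(g$score))
      }
    }
    chains <- dplyr::bind_rows(c_rows)
    chains <- merge_overlaps(chains)
  } else {
    chains <- c_hits
  }
  out <- dplyr::bind_rows(other, chains)
  out$seed_gene <- NULL; out$seed_exon <- NULL
  out[order(match(out$contig, names(genome)), out$start), , drop = FALSE]
}

#' Call segment functionality from internal stop codons
#'
#' A segment is a pseudogene (`P`) when the translation of its defined
#' reading frame (frame 1 of the spliced coding-strand sequence) contains an
#' internal stop codon; otherwise it carries an open reading frame (`ORF`).
#' The functional label `F` is assigned later, by [mark_expressed()], when a
#' transcript supports the gene. Sequences too short to hold a single codon
#' have no alignable frame and are classified `P` with reason
#' `frame-disrupted`.
#'
#' @param nt spliced nucleotide sequence (coding strand).
#' @return `"P"` or `"ORF"`; attribute `reason` set when frame-disrupted.
#' @export
call_functionality <- function(nt) {
  if (is.na(nt) || nchar(nt) < 3L) {
    out <- "P"; attr(out, "reason") <- "frame-disrupted"; return(out)
  }
  if (has_internal_stop(nt)) "P" else "ORF"
}

#' Cluster V genes into subgroups at a pairwise identity threshold
#'
#' Single-linkage clustering on pairwise global nucleotide identity
#' (ties at exactly the threshold count as within-subgroup). Clusters that
#' contain a subgroup-tagged seed inherit the seed's number; the remaining
#' clusters receive the next free numbers in order of their first member.
#'
#' @param v_nt character vector of V nucleotide sequences (input order is
#'   the order used to number novel clusters).
#' @param seeds optional seed tibble; only rows with `type == "V"` and a
#'   non-`NA` `subgroup` anchor numbering.
#' @param threshold identity threshold (default 0.75, the IMGT subgroup
#'   rule).
#' @return integer vector of subgroup labels, parallel to `v_nt`.
#' @export
cluster_subgroups <- function(v_nt, seeds = NULL, threshold = 0.75) {
  n <- length(v_nt)
  if (n == 0L) return(integer(0))
  anchor_sub <- integer(0); anchor_seq <- character(0)
  if (!is.null(seeds)) {
    sv <- seeds[seeds$type == "V" & !is.na(seeds$subgroup), , drop = FALSE]
    anchor_sub <- sv$subgroup; anchor_seq <- sv$seq
  }
  seqs <- c(anchor_seq, v_nt)
  N <- length(seqs)
  parent <- seq_len(N)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  union <- function(i, j) { ri <- find(i); rj <- find(j); if (ri != rj) parent[max(ri, rj)] <<- min(ri, rj) }
  for (i in seq_len(N - 1L)) {
    ids <- .identity_many(seqs[(i + 1L):N], seqs[i])
    for (j in which(ids >= threshold)) union(i, i + j)
  }
  roots <- vapply(seq_len(N), find, integer(1))
  labels <- integer(N)
  # anchored clusters inherit the seed subgroup
  cluster_ids <- unique(roots)
  assigned <- setNames(rep(NA_integer_, length(cluster_ids)), cluster_ids)
  for (a in seq_along(anchor_sub)) {
    r <- as.character(roots[a])
    cur <- assigned[[r]]
    if (!is.na(cur) && cur != anchor_sub[a]) {
      warning("seed subgroups ", cur, " and ", anchor_sub[a],
              " fall in one cluster; keeping ", min(cur, anchor_sub[a]))
      assigned[[r]] <- min(cur, anchor_sub[a])
    } else {
      assigned[[r]] <- anchor_sub[a]
    }
  }
  nxt <- max(c(anchor_sub, 0L)) + 1L
  for (i in seq_len(n)) {
    r <- as.character(roots[length(anchor_seq) + i])
    if (is.na(assigned[[r]])) { assigned[[r]] <- nxt; nxt <- nxt + 1L }
    labels[length(anchor_seq) + i] <- assigned[[r]]
  }
  labels[(length(anchor_seq) + 1L):N]
}

# Unit assignment: segments follow their strand, except a V gene whose
# flanking V genes (by coordinate, same contig) both belong to the opposite
# orientation: such a gene sits inside the other transcriptional unit.
assign_units <- function(segments) {
  segments$unit <- ifelse(segments$strand == "+", "fwd", "rev")
  for (ct in unique(segments$contig)) {
    vi <- which(segments$contig == ct & segments$segment_type == "V")
    vi <- vi[order(segments$start[vi])]
    if (length(vi) < 3L) next
    u <- segments$unit[vi]
    for (p in 2:(length(vi) - 1L)) {
      if (u[p] != u[p - 1L] && u[p - 1L] == u[p + 1L]) {
        segments$unit[vi[p]] <- u[p - 1L]
      }
    }
  }
  segments
}

#' Assign names following the two-orientation naming scheme
#'
#' Within a region, numbering runs separately for the two transcriptional
#' units in the V-D-J-C direction, forward-strand unit first, with `R`
#' inserted for the reverse unit. V names are
#' `{region}{R?}V{subgroup}-{ordinal}` (ordinal per subgroup per unit),
#' pseudogenes carry a `_P` extension, and segments on an unplaced scaffold
#' use `S`-suffix ordinals (`Scf.TRBV3S1`). D, J and C are
#' `{region}{R?}D`, `{region}{R?}J{n}`, `{region}{R?}C`.
#'
#' @param segments segment tibble with `unit`, `subgroup`, `functionality`
#'   columns (one region).
#' @param region_label e.g. `"TRB01"`.
#' @param scaffold logical; use the scaffold naming variant.
#' @return `segments` with a `name` column.
#' @export
assign_names <- function(segments, region_label, scaffold = FALSE) {
  bad <- segments$segment_type == "V" & is.na(segments$subgroup)
  if (any(bad)) {
    stop("assign_names: unclassified V segment(s): ",
         paste(segments$gene_id[bad] %||% which(bad), collapse = ", "))
  }
  segments$name <- NA_character_
  prefix_base <- if (scaffold) "Scf.TRB" else region_label
  for (un in c("fwd", "rev")) {
    idx <- which(segments$unit == un)
    if (length(idx) == 0L) next
    idx <- idx[order(segments$start[idx], decreasing = (un == "rev"))]
    pre <- paste0(prefix_base, if (un == "rev") "R" else "")
    v_count <- integer(0)
    j_count <- 0L
    for (i in idx) {
      tp <- segments$segment_type[i]
      if (tp == "V") {
        sg <- as.character(segments$subgroup[i])
        v_count[sg] <- (if (is.na(v_count[sg])) 0L else v_count[sg]) + 1L
        nm <- if (scaffold) {
          paste0(pre, "V", sg, "S", v_count[sg])
        } else {
          paste0(pre, "V", sg, "-", v_count[sg])
        }
        if (identical(segments$functionality[i], "P")) nm <- paste0(nm, "_P")
      } else if (tp == "J") {
        j_count <- j_count + 1L
        nm <- paste0(pre, "J", j_count)
      } else if (tp == "D") {
        nm <- paste0(pre, "D")
      } else {
        nm <- paste0(pre, "C")
      }
      segments$name[i] <- nm
    }
  }
  if (anyDuplicated(segments$name)) {
    stop("assign_names produced duplicate names")
  }
  segments
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Recover the leader exon of a V gene
#'
#' Enumerates ATG-initiated, codon-aligned exons in the upstream window that
#' end at a canonical GT splice donor, require an AG acceptor immediately
#' before the V exon, and whose spliced translation runs stop-free into the
#' V frame. The stop-free candidate with the longest open reading frame
#' wins; ties go to the candidate nearest the V exon.
#'
#' @param contig_seq contig sequence (forward strand).
#' @param v_start,v_end V exon interval, 0-based half-open, forward strand.
#' @param strand `"+"` or `"-"`.
#' @param v_nt V exon sequence on the coding strand.
#' @param window upstream search window (nt).
#' @param min_exon minimum leader exon length.
#' @return list with `start`, `end` (0-based half-open, forward strand) and
#'   `exon_seq`, or `NULL` when no candidate exists.
#' @export
find_leader <- function(contig_seq, v_start, v_end, strand, v_nt,
                        window = 400L, min_exon = 18L) {
  Lc <- nchar(contig_seq)
  if (strand == "+") {
    if (v_start < window) {
      warning("leader window truncated by contig edge"); return(NULL)
    }
    U <- substr(contig_seq, v_start - window + 1L, v_start)
  } else {
    if (Lc - v_end < window) {
      warning("leader window truncated by contig edge"); return(NULL)
    }
    U <- revcomp(substr(contig_seq, v_end + 1L, v_end + window))
  }
  w <- nchar(U)
  if (substr(U, w - 1L, w) != "AG") return(NULL)  # no acceptor before the V exon
  atg <- gregexpr("ATG", U, fixed = TRUE)[[1]]
  if (atg[1] == -1L) return(NULL)
  gt <- gregexpr("GT", U, fixed = TRUE)[[1]]
  if (gt[1] == -1L) return(NULL)
  best <- NULL
  for (p in as.integer(atg)) {
    for (q in as.integer(gt)) {
      len <- q - p
      if (len < min_exon || len %% 3L != 0L) next
      if (q + 1L > w - 2L) next  # leave room for the intron and acceptor
      splice <- paste0(substr(U, p, q - 1L), v_nt)
      aa <- translate_nt(splice)
      if (grepl("*", substr(aa, 1L, nchar(aa) - 1L), fixed = TRUE)) next
      if (is.null(best) || len > best$len || (len == best$len && p > best$p)) {
        best <- list(p = p, q = q, len = len, exon_seq = substr(U, p, q - 1L))
      }
    }
  }
  if (is.null(best)) return(NULL)
  if (strand == "+") {
    gs <- v_start - window + best$p - 1L
    ge <- v_start - window + best$q - 1L
  } else {
    gs <- v_end + window - (best$q - 1L)
    ge <- v_end + window - (best$p - 1L)
  }
  list(start = gs, end = ge, exon_seq = best$exon_seq)
}

#' Annotate a genome end to end
#'
#' Runs candidate mining, subgroup clustering (global across regions, so
#' shared subgroups keep one number), functionality calling, unit
#' assignment, leader recovery and naming.
#'
#' @param genome named character vector / `DNAStringSet` / FASTA path.
#' @param seeds seed library (see [read_seeds()]).
#' @param region_map tibble `contig`, `region_label`, `scaffold`; defaults
#'   to one region per contig named after it.
#' @param threshold subgroup identity threshold.
#' @param leader_window upstream leader search window.
#' @param ... passed to [find_candidates()].
#' @return object of class `trb_annotation`: list with `segments` (named,
#'   classified tibble) and `region_map`.
#' @export
annotate_genome <- function(genome, seeds, region_map = NULL,
                            threshold = 0.75, leader_window = 400L, ...) {
  genome <- .as_genome(genome)
  if (is.character(seeds) || is(seeds, "DNAStringSet")) seeds <- read_seeds(seeds)
  if (is.null(region_map)) {
    region_map <- tibble(contig = names(genome),
                         region_label = toupper(names(genome)),
                         scaffold = FALSE)
  }
  segs <- find_candidates(genome, seeds, ...)
  if (nrow(segs) == 0L) {
    return(structure(list(segments = segs, region_map = region_map),
                     class = "trb_annotation"))
  }
  segs <- dplyr::left_join(segs, region_map, by = "contig")
  segs <- segs[order(match(segs$contig, region_map$contig), segs$start), ]

  vi <- which(segs$segment_type == "V")
  segs$subgroup <- NA_integer_
  if (length(vi) > 0L) {
    segs$subgroup[vi] <- cluster_subgroups(segs$nt[vi], seeds, threshold = threshold)
  }
  segs$functionality <- vapply(seq_len(nrow(segs)), function(i) {
    if (segs$segment_type[i] %in% c("V", "C")) as.character(call_functionality(segs$nt[i]))
    else "ORF"
  }, character(1))
  segs <- assign_units(segs)

  segs$leader_start <- NA_integer_
  segs$leader_end <- NA_integer_
  for (i in vi) {
    led <- find_leader(genome[[segs$contig[i]]], segs$start[i], segs$end[i],
                       segs$strand[i], segs$nt[i], window = leader_window)
    if (!is.null(led)) {
      segs$leader_start[i] <- led$start
      segs$leader_end[i] <- led$end
    }
  }

  named <- list()
  for (ri in seq_len(nrow(region_map))) {
    rseg <- segs[segs$contig == region_map$contig[ri], , drop = FALSE]
    if (nrow(rseg) == 0L) next
    named[[ri]] <- assign_names(rseg, region_map$region_label[ri],
                                scaffold = region_map$scaffold[ri])
  }
  segs <- dplyr::bind_rows(named)
  structure(list(segments = segs, region_map = region_map),
            class = "trb_annotation")
}

#' @export
print.trb_annotation <- function(x, ...) {
  s <- x$segments
  cat("TRB annotation:", nrow(s), "segments over",
      length(unique(s$contig)), "contig(s)\n")
  if (nrow(s) > 0L) {
    tab <- table(s$region_label, s$segment_type)
    print(tab)
  }
  invisible(x)
}
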