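# Shared fixtures (memoized: the heavier simulations are built once per run)
# and independent oracle implementations used to cross-check the package's
# algorithms. Oracles deliberately use naive string loops / matrix closures,
# not the code paths they verify.

.fx <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fx)) assign(key, force(expr), envir = .fx)
  get(key, envir = .fx)
}

tiny_plan <- function() {
  tibble::tribble(
    ~region,  ~subgroup, ~n, ~n_pseudo, ~n_expressed,
    "TRB01",  3L, 4L, 1L, 2L,
    "TRB01", 11L, 2L, 0L, 1L,
    "TRB09",  1L, 2L, 0L, 1L,
    "TRB09",  3L, 3L, 1L, 1L,
    "TRB09", 13L, 2L, 0L, 1L
  )
}

tiny_config <- function(seed = 42L, ...) {
  args <- list(...)
  base <- list(seed = seed, v_plan = tiny_plan(),
               n_forward = c(TRB01 = 1L, TRB09 = 2L),
               clonotypes_per_gene = 2L, reads_per_clonotype = 25L)
  do.call(sim_config, utils::modifyList(base, args))
}

tiny_sim <- function() memo("tiny_sim", simulate_locus(tiny_config()))

tiny_ann <- function() memo("tiny_ann", {
  s <- tiny_sim()
  annotate_genome(s$genome, s$seeds, region_map = s$region_map)
})

# default study-scale simulation (the census conditions)
full_sim <- function() memo("full_sim", simulate_locus(sim_config()))

full_ann <- function() memo("full_ann", {
  s <- full_sim()
  annotate_genome(s$genome, s$seeds, region_map = s$region_map)
})

# error-free repertoire run over the default simulation
full_repertoire <- function() memo("full_rep", {
  s <- full_sim(); ann <- full_ann()
  amp <- simulate_amplicons(s, error_rate = 0)
  pairs <- quality_trim(amp$pairs)
  dm <- demultiplex(pairs, s$primers)
  segs <- ann$segments
  c_refs <- stats::setNames(
    segs$nt[segs$segment_type == "C" & segs$unit == "fwd"],
    segs$region_label[segs$segment_type == "C" & segs$unit == "fwd"])
  col <- list()
  for (bn in names(dm$bins)) {
    mg <- merge_pairs(dm$bins[[bn]])
    lab <- gsub("\\.F[0-9]*\\|", ".", sub("\\.R$", "", bn))
    col[[bn]] <- collapse_reads(mg$sequence, lab)
  }
  collapsed <- dplyr::bind_rows(col)
  collapsed <- orf_filter(collapsed, c_refs)
  clono <- assign_germline(collapsed, ann)
  marked <- mark_expressed(ann, clono, min_support = 20)
  list(amp = amp, clonotypes = clono, marked = marked, c_refs = c_refs)
})

# map truth gene ids to assigned names via exact coordinates
truth_name_map <- function(sim, ann) {
  tv <- sim$truth$segments
  av <- ann$segments
  key_t <- paste(tv$contig, tv$start)
  key_a <- paste(av$contig, av$start)
  stats::setNames(av$name[match(key_t, key_a)], tv$gene_id)
}

# ---- independent oracles --------------------------------------------------

# naive Hamming identity for equal-length, gap-free sequences
hamming_identity <- function(a, b) {
  va <- strsplit(a, "")[[1]]; vb <- strsplit(b, "")[[1]]
  mean(va == vb)
}

# transitive closure of the >= threshold relation by repeated boolean
# matrix multiplication (brute force single-linkage oracle)
closure_partition <- function(idmat, threshold) {
  A <- idmat >= threshold
  diag(A) <- TRUE
  repeat {
    A2 <- (A %*% A) > 0
    if (identical(A2, A)) break
    A <- A2
  }
  match(apply(A, 1, function(r) paste(which(r), collapse = ",")),
        unique(apply(A, 1, function(r) paste(which(r), collapse = ","))))
}

# naive per-pair recount for distances (pairwise deletion)
naive_p_matrix <- function(seqs, ambiguous) {
  m <- do.call(rbind, strsplit(seqs, ""))
  n <- nrow(m)
  P <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    ok <- !(m[i, ] %in% ambiguous) & !(m[j, ] %in% ambiguous)
    P[i, j] <- sum(m[i, ok] != m[j, ok]) / sum(ok)
  }
  P
}

# exhaustive-search optimum of templated nucleotides for a junction
# decomposition: enumerates every (v-trim, j-match, D-placement)
# combination; the window extends a little beyond the provable bound used
# by the implementation, so it also checks that bound.
junction_oracle_total <- function(sequence, v_nt, j_tbl, d_core, c_pos,
                                  min_d_match = 4L, min_j_anchor = 8L,
                                  back = NULL) {
  if (is.null(back)) back <- nchar(d_core) + 3L
  npre <- function(a, b) { n <- 0L
    while (n < min(nchar(a), nchar(b)) &&
           substr(a, n + 1L, n + 1L) == substr(b, n + 1L, n + 1L)) n <- n + 1L
    n }
  nsuf <- function(a, b) { n <- 0L
    while (n < min(nchar(a), nchar(b)) &&
           substr(a, nchar(a) - n, nchar(a) - n) ==
           substr(b, nchar(b) - n, nchar(b) - n)) n <- n + 1L
    n }
  cc <- utf8ToInt(d_core); nc <- length(cc)
  lcs_dp <- function(x) {
    if (!nzchar(x)) return(0L)
    xv <- utf8ToInt(x)
    best <- 0L; L <- integer(nc)
    for (i in seq_along(xv)) {
      L <- ifelse(xv[i] == cc, c(0L, L[-nc]) + 1L, 0L)
      best <- max(best, L)
    }
    best
  }
  upto <- substr(sequence, 1L, c_pos - 1L)
  m_v <- npre(sequence, v_nt)
  raws <- vapply(j_tbl$nt, function(j) nsuf(upto, j), integer(1))
  mx <- if (length(raws)) max(raws) else 0L
  best_total <- -1L
  for (va in max(0L, m_v - back):m_v) {
    top <- min(mx, nchar(upto) - va)
    if (top < min_j_anchor) next
    for (mj in min_j_anchor:top) {
      middle <- if (c_pos - 1L - mj >= va + 1L)
        substr(sequence, va + 1L, c_pos - 1L - mj) else ""
      dl <- lcs_dp(middle)
      if (dl < min_d_match) dl <- 0L
      best_total <- max(best_total, va + mj + dl)
    }
  }
  best_total
}

# random coding sequence helper for constructed cases
rand_cds <- function(n_codons) {
  gc <- Biostrings::GENETIC_CODE
  sense <- names(gc)[gc != "*"]
  paste(sample(sense, n_codons, replace = TRUE), collapse = "")
}

rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE), collapse = "")
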