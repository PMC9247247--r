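# ---------------------------------------------------------------------------
# Census rendering, GFF3 / AIRR / FASTA artifacts and pipeline orchestration.
# ---------------------------------------------------------------------------

#' Render the V-gene census (subgroup x region)
#'
#' Counts V genes per subgroup and region with pseudogene counts in a
#' separate column, plus totals row and columns. Totals are asserted to
#' equal the marginal sums.
#'
#' @param annotation a `trb_annotation`, or a segment tibble with
#'   `segment_type`, `subgroup`, `region_label`, `functionality`.
#' @return tibble: `subgroup`, then `{region}_n` / `{region}_p` per region,
#'   `total_n`, `total_p`; last row `Total`.
#' @export
render_census <- function(annotation) {
  segs <- if (inherits(annotation, "trb_annotation")) annotation$segments else annotation
  regions <- unique(segs$region_label)
  v <- segs[segs$segment_type == "V", , drop = FALSE]
  subs <- sort(unique(v$subgroup))
  out <- tibble(subgroup = c(sprintf("V%d", subs), "Total"))
  for (r in regions) {
    nn <- integer(length(subs)); pp <- integer(length(subs))
    for (k in seq_along(subs)) {
      sel <- v$region_label == r & v$subgroup == subs[k]
      nn[k] <- sum(sel)
      pp[k] <- sum(sel & v$functionality == "P")
    }
    out[[paste0(r, "_n")]] <- c(nn, sum(nn))
    out[[paste0(r, "_p")]] <- c(pp, sum(pp))
  }
  ncols <- sprintf("%s_n", regions); pcols <- sprintf("%s_p", regions)
  out$total_n <- rowSums(as.matrix(out[, ncols, drop = FALSE]))
  out$total_p <- rowSums(as.matrix(out[, pcols, drop = FALSE]))
  last <- nrow(out)
  stopifnot(out$total_n[last] == sum(out$total_n[-last]),
            out$total_p[last] == sum(out$total_p[-last]))
  out
}

#' Text rendering of a census with parenthesized pseudogene counts
#' @param census tibble from [render_census()].
#' @return character vector of lines.
#' @export
census_text <- function(census) {
  regions <- sub("_n$", "", grep("_n$", names(census), value = TRUE))
  regions <- setdiff(regions, "total")
  fmt_cell <- function(n, p) {
    ifelse(n == 0 & p == 0, "-",
           ifelse(p > 0, sprintf("%d (%d)", n, p), sprintf("%d", n)))
  }
  hdr <- paste(c(sprintf("%-10s", "Subgroup"),
                 sprintf("%12s", c(regions, "Total"))), collapse = "")
  lines <- hdr
  for (i in seq_len(nrow(census))) {
    cells <- vapply(regions, function(r)
      fmt_cell(census[[paste0(r, "_n")]][i], census[[paste0(r, "_p")]][i]),
      character(1))
    tot <- fmt_cell(census$total_n[i], census$total_p[i])
    lines <- c(lines, paste(c(sprintf("%-10s", census$subgroup[i]),
                              sprintf("%12s", c(cells, tot))), collapse = ""))
  }
  lines
}

#' Export an annotation as GFF3
#'
#' One `gene` feature per segment with `ID`, `Name` and `functionality`
#' attributes (1-based coordinates, as GFF requires).
#'
#' @param annotation a `trb_annotation`.
#' @param path output `.gff3` path.
#' @return `path`, invisibly.
#' @export
export_gff3 <- function(annotation, path) {
  segs <- annotation$segments
  gr <- GenomicRanges::GRanges(
    seqnames = segs$contig,
    ranges = IRanges::IRanges(start = segs$start + 1L, end = segs$end),
    strand = segs$strand)
  S4Vectors::mcols(gr)$type <- "gene"
  S4Vectors::mcols(gr)$ID <- segs$name
  S4Vectors::mcols(gr)$Name <- segs$name
  S4Vectors::mcols(gr)$functionality <- segs$functionality
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Write clonotypes as an AIRR-style rearrangement TSV
#'
#' Columns: `sequence_id`, `sequence`, `v_call`, `d_call`, `j_call`,
#' `c_call`, `junction`, `junction_aa`, `np1_length`, `np2_length`,
#' `duplicate_count`.
#'
#' @param clonotypes tibble from [decompose_all()].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_airr <- function(clonotypes, path) {
  cols <- tibble(
    sequence_id = clonotypes$sequence_id,
    sequence = clonotypes$sequence,
    v_call = clonotypes$v_call,
    d_call = if ("d_call" %in% names(clonotypes)) clonotypes$d_call else NA,
    j_call = if ("j_call" %in% names(clonotypes)) clonotypes$j_call else NA,
    c_call = clonotypes$c_call,
    junction = if ("junction" %in% names(clonotypes)) clonotypes$junction else NA,
    junction_aa = if ("junction_aa" %in% names(clonotypes)) clonotypes$junction_aa else NA,
    np1_length = if ("np1_length" %in% names(clonotypes)) clonotypes$np1_length else NA,
    np2_length = if ("np2_length" %in% names(clonotypes)) clonotypes$np2_length else NA,
    duplicate_count = clonotypes$count
  )
  write.table(cols, path, sep = "\t", quote = FALSE, row.names = FALSE, na = "")
  invisible(path)
}

#' Pipeline configuration
#'
#' Validated, YAML-serializable configuration for [run_pipeline()]. Unknown
#' keys are rejected.
#'
#' @param out_dir output directory.
#' @param seed master seed.
#' @param stages stages to run, in dependency order.
#' @param sim named list of [sim_config()] overrides.
#' @param genome_fa,seeds_fa,fastq_r1,fastq_r2 input paths when the
#'   simulate stage is off.
#' @param min_support expressed-support read threshold.
#' @param bootstrap_replicates bootstrap replicates for the tree stage.
#' @param tree_model distance model for the V tree.
#' @param min_identity,min_coverage candidate-mining thresholds.
#' @param log_level `"info"` or `"quiet"`.
#' @return list of class `trb_pipeline_config`.
#' @export
pipeline_config <- function(out_dir = "trbkit_out",
                            seed = 101L,
                            stages = c("simulate", "annotate", "tree",
                                       "amplicons", "junctions", "report"),
                            sim = list(),
                            genome_fa = NULL, seeds_fa = NULL,
                            fastq_r1 = NULL, fastq_r2 = NULL,
                            min_support = 20L,
                            bootstrap_replicates = 200L,
                            tree_model = "poisson",
                            min_identity = 0.70,
                            min_coverage = 0.60,
                            log_level = "info") {
  cfg <- as.list(environment())
  known_stages <- c("simulate", "annotate", "tree", "amplicons", "junctions", "report")
  if (length(setdiff(cfg$stages, known_stages)) > 0L) {
    stop("unknown stage(s): ", paste(setdiff(cfg$stages, known_stages), collapse = ", "))
  }
  if (length(cfg$sim) > 0L) {
    bad <- setdiff(names(cfg$sim), names(formals(sim_config)))
    if (length(bad) > 0L) stop("unknown sim key(s): ", paste(bad, collapse = ", "))
  }
  cfg$schema <- "trbkit-pipeline-1"
  class(cfg) <- "trb_pipeline_config"
  cfg
}

#' Read / write pipeline configuration YAML
#' @param path YAML file.
#' @return a `trb_pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  raw$schema <- NULL
  known <- names(formals(pipeline_config))
  bad <- setdiff(names(raw), known)
  if (length(bad) > 0L) stop("unknown config key(s): ", paste(bad, collapse = ", "))
  do.call(pipeline_config, raw)
}

#' @rdname read_pipeline_config
#' @param config a `trb_pipeline_config`.
#' @export
write_pipeline_config <- function(config, path) {
  x <- unclass(config)
  yaml::write_yaml(x, path)
  invisible(path)
}

.log_msg <- function(cfg, ...) {
  if (identical(cfg$log_level, "quiet")) return(invisible())
  message(format(Sys.time(), "%H:%M:%S"), " [trbkit] ", ...)
}

#' Run the full pipeline
#'
#' Executes the configured stages in dependency order
#' (simulate/annotate -> tree -> amplicons -> junctions -> report), writing
#' `genome.fa`, `seeds.fa`, `census.tsv`, `annotation.gff3`, `tree.nwk`,
#' `collapsed.fasta`, `clonotypes.tsv`, `j_usage.tsv` and a checksummed
#' `manifest.tsv` under `out_dir`. Reruns with the same configuration and
#' inputs are byte-identical.
#'
#' @param config a [pipeline_config()].
#' @return list with the in-memory objects and the manifest tibble.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "trb_pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  art <- character(0)
  res <- list()
  emit <- function(path) art <<- c(art, path)

  sim <- NULL; genome <- NULL; seeds <- NULL; region_map <- NULL
  primers <- NULL

  if ("simulate" %in% config$stages) {
    .log_msg(config, "simulate: building dual-locus genome")
    sc <- do.call(sim_config, c(list(seed = config$seed), config$sim))
    sim <- simulate_locus(sc)
    genome <- sim$genome; seeds <- sim$seeds
    region_map <- sim$region_map; primers <- sim$primers
    gf <- file.path(config$out_dir, "genome.fa")
    gs <- Biostrings::DNAStringSet(genome); names(gs) <- names(genome)
    Biostrings::writeXStringSet(gs, gf); emit(gf)
    sf <- file.path(config$out_dir, "seeds.fa")
    write_seeds(seeds, sf); emit(sf)
    tt <- sim$truth$segments
    tt$exon_starts <- vapply(tt$exon_starts, paste, character(1), collapse = ",")
    tt$exon_ends <- vapply(tt$exon_ends, paste, character(1), collapse = ",")
    tf <- file.path(config$out_dir, "truth_segments.tsv")
    write.table(tt, tf, sep = "\t", quote = FALSE, row.names = FALSE); emit(tf)
    res$sim <- sim
  } else {
    if (is.null(config$genome_fa) || !file.exists(config$genome_fa)) {
      stop("annotate stage needs genome_fa; missing: ",
           config$genome_fa %||% "<unset>")
    }
    if (is.null(config$seeds_fa) || !file.exists(config$seeds_fa)) {
      stop("annotate stage needs seeds_fa; missing: ",
           config$seeds_fa %||% "<unset>")
    }
    genome <- .as_genome(config$genome_fa)
    seeds <- read_seeds(config$seeds_fa)
  }

  ann <- NULL
  if ("annotate" %in% config$stages) {
    .log_msg(config, "annotate: mining segments")
    ann <- annotate_genome(genome, seeds, region_map = region_map,
                           min_identity = config$min_identity,
                           min_coverage = config$min_coverage)
    cen <- render_census(ann)
    cf <- file.path(config$out_dir, "census.tsv")
    write.table(cen, cf, sep = "\t", quote = FALSE, row.names = FALSE); emit(cf)
    ctf <- file.path(config$out_dir, "census.txt")
    writeLines(census_text(cen), ctf); emit(ctf)
    gff <- file.path(config$out_dir, "annotation.gff3")
    export_gff3(ann, gff); emit(gff)
    res$annotation <- ann; res$census <- cen
  }

  if ("tree" %in% config$stages && !is.null(ann)) {
    .log_msg(config, "tree: verifying V families (NJ, ",
             config$bootstrap_replicates, " bootstrap replicates)")
    v <- ann$segments[ann$segments$segment_type == "V", ]
    # one representative per (region, subgroup); equal-length V exons from
    # the mining step act as the pre-aligned input
    key <- paste(v$region_label, v$subgroup)
    rep_idx <- vapply(split(seq_len(nrow(v)), key), function(ix)
      ix[which.max(v$end[ix] - v$start[ix])], integer(1))
    reps <- v[rep_idx, ]
    lens <- nchar(reps$nt)
    keep <- lens == stats::median(lens)
    reps <- reps[keep, ]
    aln <- if (config$tree_model == "poisson") {
      setNames(vapply(reps$nt, translate_nt, character(1)), reps$name)
    } else {
      setNames(reps$nt, reps$name)
    }
    tr <- bootstrap_support(aln, model = config$tree_model,
                            replicates = config$bootstrap_replicates,
                            seed = config$seed)
    tfp <- file.path(config$out_dir, "tree.nwk")
    ape::write.tree(tr, tfp); emit(tfp)
    res$tree <- tr
  }

  clono <- NULL
  if ("amplicons" %in% config$stages && !is.null(ann)) {
    if (!is.null(sim)) {
      .log_msg(config, "amplicons: simulating expressed repertoire reads")
      amp <- simulate_amplicons(sim)
      pairs <- amp$pairs
      primers_use <- primers
      res$amplicon_truth <- amp
      fq <- file.path(config$out_dir, "reads")
      write_fastq_pairs(pairs, fq)
      emit(paste0(fq, "_R1.fastq")); emit(paste0(fq, "_R2.fastq"))
    } else {
      if (is.null(config$fastq_r1) || !file.exists(config$fastq_r1) ||
          is.null(config$fastq_r2) || !file.exists(config$fastq_r2)) {
        stop("amplicon stage needs fastq_r1/fastq_r2; missing: ",
             paste(c(config$fastq_r1, config$fastq_r2), collapse = ", "))
      }
      pairs <- read_fastq_pairs(config$fastq_r1, config$fastq_r2)
      primers_use <- trb_primers()
    }
    .log_msg(config, "amplicons: trim, demultiplex, merge, collapse")
    pairs <- quality_trim(pairs)
    dm <- demultiplex(pairs, primers_use)
    c_refs <- setNames(
      ann$segments$nt[ann$segments$segment_type == "C" & ann$segments$unit == "fwd"],
      ann$segments$region_label[ann$segments$segment_type == "C" &
                                  ann$segments$unit == "fwd"])
    c_refs <- c_refs[!duplicated(names(c_refs))]
    per_bin <- list()
    for (bn in names(dm$bins)) {
      merged <- merge_pairs(dm$bins[[bn]])
      lab <- gsub("\\.F[0-9]*\\|", ".", sub("\\.R$", "", bn))
      col <- collapse_reads(merged$sequence, primer_pair = lab)
      if (nrow(col) > 0L) per_bin[[bn]] <- col
    }
    collapsed <- dplyr::bind_rows(per_bin)
    if (nrow(collapsed) > 0L) {
      collapsed <- orf_filter(collapsed, c_refs)
      clono <- assign_germline(collapsed, ann)
      marked <- mark_expressed(ann, clono, min_support = config$min_support)
      ann <- marked$annotation
      res$annotation <- ann
      res$conflicts <- marked$conflicts
      # refresh census with F labels available
      cen <- render_census(ann)
      cf <- file.path(config$out_dir, "census.tsv")
      write.table(cen, cf, sep = "\t", quote = FALSE, row.names = FALSE)
      res$census <- cen
      fa <- file.path(config$out_dir, "collapsed.fasta")
      ss <- Biostrings::DNAStringSet(collapsed$sequence)
      names(ss) <- collapsed$sequence_id
      Biostrings::writeXStringSet(ss, fa); emit(fa)
    }
    res$clonotypes <- clono
  }

  if ("junctions" %in% config$stages && !is.null(clono)) {
    .log_msg(config, "junctions: decomposing CDR3 regions")
    clono <- decompose_all(clono, ann)
    res$clonotypes <- clono
    ct <- file.path(config$out_dir, "clonotypes.tsv")
    write_airr(clono, ct); emit(ct)
    ju <- tally_j_usage(clono, ann)
    jf <- file.path(config$out_dir, "j_usage.tsv")
    write.table(ju, jf, sep = "\t", quote = FALSE, row.names = FALSE); emit(jf)
    res$j_usage <- ju
  }

  if ("report" %in% config$stages) {
    art <- unique(art)
    manifest <- tibble(file = basename(art),
                       md5 = unname(tools::md5sum(art)))
    mf <- file.path(config$out_dir, "manifest.tsv")
    write.table(manifest, mf, sep = "\t", quote = FALSE, row.names = FALSE)
    res$manifest <- manifest
    .log_msg(config, "report: ", nrow(manifest), " artifacts in ", config$out_dir)
  }
  res
}
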