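# ---------------------------------------------------------------------------
# Synthetic dual-locus TRB genomes and recombined amplicon reads.
#
# The generator emulates the architecture the annotation pipeline assumes:
# two diverged paralogous regions (plus an unplaced scaffold haplotype), each
# carrying dual V-D-J-C transcriptional units in opposite orientations,
# V subgroups respecting the 75% nucleotide-identity rule, pseudogenes with
# planted internal stops, inverted sequence-identical J duplicates, a single
# shared D core, and recombined amplicons with exonuclease trimming,
# non-templated N insertions and sequencing error.
# ---------------------------------------------------------------------------

.random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

.random_cds <- function(n_codons) {
  paste(sample(.SENSE_CODONS, n_codons, replace = TRUE), collapse = "")
}

# Remove start codons on both strands (ATG forward, CAT = reverse-strand ATG)
# so that intergenic sequence can never out-compete a planted leader exon.
.scrub_atg <- function(s) {
  while (grepl("ATG", s, fixed = TRUE) || grepl("CAT", s, fixed = TRUE)) {
    s <- gsub("ATG", "ATC", s, fixed = TRUE)
    s <- gsub("CAT", "CTT", s, fixed = TRUE)
  }
  s
}

# Intron with canonical GT..AG ends and a G-free interior: no internal splice
# donors, no start codons, stop codons in every frame almost immediately.
.make_intron <- function(len) {
  stopifnot(len >= 6)
  paste0("GT", paste(sample(c("A", "C", "T"), len - 4, TRUE), collapse = ""), "AG")
}

# Per-site substitution with a 2:1 transition bias. `n` sites are drawn from
# the eligible positions (all but `protect`); divergence is applied as an
# exact count so planted identities are reproducible. Substitutions that
# create an in-frame stop codon are reverted (pseudogene stops are planted
# explicitly, never by accident).
.mutate_seq <- function(seq, rate = NULL, n = NULL, protect = integer(0),
                        coding = TRUE) {
  v <- strsplit(seq, "", fixed = TRUE)[[1]]
  eligible <- setdiff(seq_along(v), protect)
  if (is.null(n)) n <- round(rate * length(eligible))
  if (n <= 0L) return(seq)
  n <- min(n, length(eligible))
  pos <- sample(eligible, n)
  transition <- c(A = "G", G = "A", C = "T", T = "C")
  tv <- list(A = c("C", "T"), G = c("C", "T"), C = c("A", "G"), T = c("A", "G"))
  orig <- v
  for (p in pos) {
    b <- v[p]
    if (!b %in% names(transition)) next
    v[p] <- sample(c(transition[[b]], tv[[b]]), 1L, prob = c(2, 1, 1))
  }
  if (coding) {
    nc <- length(v) %/% 3L
    for (ci in seq_len(nc)) {
      idx <- (3L * ci - 2L):(3L * ci)
      if (paste(v[idx], collapse = "") %in% .STOP_CODONS &&
          !paste(orig[idx], collapse = "") %in% .STOP_CODONS) {
        v[idx] <- orig[idx]
      }
    }
  }
  paste(v, collapse = "")
}

# Replace `n` codons with codons encoding a different amino acid: the planted
# protein divergence is then exact, which is how the paralogous constant
# domains are tuned to a target amino-acid identity.
.diverge_codons_aa <- function(seq, n, protect_codons = integer(0)) {
  nc <- nchar(seq) %/% 3L
  codons <- substring(seq, 3L * seq_len(nc) - 2L, 3L * seq_len(nc))
  eligible <- setdiff(seq_len(nc), protect_codons)
  pick <- sample(eligible, min(n, length(eligible)))
  for (ci in pick) {
    aa <- .GENETIC_CODE[codons[ci]]
    alt <- .SENSE_CODONS[.GENETIC_CODE[.SENSE_CODONS] != aa]
    codons[ci] <- sample(alt, 1L)
  }
  paste(codons, collapse = "")
}

.default_v_plan <- function() {
  tibble::tribble(
    ~region,  ~subgroup, ~n, ~n_pseudo, ~n_expressed,
    "TRB01",  3L,  22L, 0L, 10L,
    "TRB01",  4L,   3L, 1L,  0L,
    "TRB01",  5L,   2L, 1L,  0L,
    "TRB01", 10L,   9L, 1L,  2L,
    "TRB01", 11L,  15L, 0L,  6L,
    "Scf",    3L,   7L, 0L,  0L,
    "Scf",   10L,   3L, 0L,  0L,
    "Scf",   11L,   9L, 3L,  0L,
    "TRB09",  1L,   8L, 4L,  2L,
    "TRB09",  2L,   9L, 0L,  5L,
    "TRB09",  3L,  10L, 3L,  7L,
    "TRB09",  4L,   3L, 0L,  3L,
    "TRB09",  5L,   8L, 4L,  4L,
    "TRB09",  6L,   1L, 1L,  0L,
    "TRB09",  7L,   3L, 0L,  2L,
    "TRB09",  8L,   1L, 0L,  1L,
    "TRB09",  9L,   1L, 0L,  1L,
    "TRB09", 12L,   1L, 0L,  0L,
    "TRB09", 13L,   4L, 0L,  1L
  )
}

#' Simulation configuration
#'
#' Defaults describe the dual-locus architecture the annotation census is
#' checked against: a 51-gene region, a 49-gene paralogous region and a
#' 19-gene unplaced scaffold haplotype (119 V genes, 18 pseudogenes, 12 of
#' them in the second region), paralogous constant domains diverged at one
#' third of codons (67% amino-acid identity), identical diversity cores in
#' every unit, and 26 of 49 second-region V genes carrying expressed support.
#'
#' @param seed integer; fixes every downstream draw.
#' @param v_plan tibble with columns `region`, `subgroup`, `n`, `n_pseudo`,
#'   `n_expressed`: the V-gene census to plant.
#' @param n_forward named integer vector: V genes allocated to the forward
#'   transcriptional unit per region (the remainder go to the reverse unit).
#' @param v_exon_length,leader_length,intron_length,j_length,c_length
#'   segment geometry in nucleotides (all multiples of 3 where translated).
#' @param gene_spacing intergenic spacer length (>= 450 so a leader search
#'   window never reaches the upstream gene).
#' @param within_subgroup_divergence per-site substitution divergence of a
#'   gene from its subgroup ancestor (<= 0.25 keeps the subgroup above the
#'   75% identity rule).
#' @param between_region_divergence per-site divergence between the two
#'   chromosomal copies of a subgroup ancestor.
#' @param subgroup_divergence per-site divergence of each subgroup ancestor
#'   from the root V (drives between-subgroup separation well below 75%).
#' @param novel_pair_divergence per-site divergence of each of the two
#'   whole-genome-duplication novel paralogue subgroups from their common
#'   ancestor (lands their cross identity below the subgroup threshold).
#' @param c_aa_divergence fraction of constant-domain codons replaced with a
#'   different amino acid between regions (0.33 -> 67% aa identity).
#' @param scaffold_identical_fraction fraction of scaffold V genes copied
#'   byte-identically from region-1 genes (creates the ambiguous
#'   multi-gene 100% matches seen in expressed data).
#' @param n_j named list: forward/reverse J counts per region.
#' @param j_inverted_identical named list of J indices whose reverse-unit
#'   copy is sequence-identical to the forward-unit gene.
#' @param d_core diversity core sequence, identical in every unit.
#' @param c_exons named integer vector: constant-gene exon counts per region.
#' @param trim_geom_p geometric(p) parameter for exonuclease trimming.
#' @param max_trim cap on V/J trimming (nt).
#' @param n_insertion_max non-templated insertion lengths are uniform on
#'   `0:n_insertion_max`.
#' @param clonotypes_per_gene,reads_per_clonotype amplicon sampling depth.
#' @param read_length paired-end read length.
#' @param error_rate per-base sequencing error rate.
#' @param primer_length gene-specific forward-primer length (first bases of
#'   the V exon, held invariant within a subgroup).
#' @param c_amplicon_length constant-gene prefix included in each amplicon.
#' @param expressed_pseudogene plant expression on one pseudogene to exercise
#'   status-conflict reporting.
#' @return object of class `trb_sim_config` (a validated list).
#' @export
sim_config <- function(seed = 101L,
                       v_plan = .default_v_plan(),
                       n_forward = c(TRB01 = 3L, Scf = 4L, TRB09 = 17L),
                       v_exon_length = 288L,
                       leader_length = 48L,
                       intron_length = 81L,
                       j_length = 51L,
                       c_length = 510L,
                       gene_spacing = 600L,
                       within_subgroup_divergence = 0.04,
                       between_region_divergence = 0.04,
                       subgroup_divergence = 0.30,
                       novel_pair_divergence = 0.18,
                       c_aa_divergence = 0.33,
                       scaffold_identical_fraction = 0.5,
                       n_j = list(fwd = c(TRB01 = 9L, TRB09 = 10L),
                                  rev = c(TRB01 = 7L, TRB09 = 10L)),
                       j_inverted_identical = list(TRB01 = c(1L, 4L, 5L, 6L),
                                                   TRB09 = c(2L, 3L, 4L, 6L, 8L)),
                       d_core = "GGACAGGGGGGC",
                       c_exons = c(TRB01 = 3L, TRB09 = 4L),
                       trim_geom_p = 0.4,
                       max_trim = 6L,
                       n_insertion_max = 10L,
                       clonotypes_per_gene = 3L,
                       reads_per_clonotype = 30L,
                       read_length = 250L,
                       error_rate = 0.001,
                       primer_length = 20L,
                       c_amplicon_length = 60L,
                       expressed_pseudogene = FALSE) {
  cfg <- as.list(environment())
  fr <- c("within_subgroup_divergence", "between_region_divergence",
          "subgroup_divergence", "novel_pair_divergence", "c_aa_divergence",
          "scaffold_identical_fraction", "trim_geom_p", "error_rate")
  for (f in fr) {
    if (cfg[[f]] < 0 || cfg[[f]] > 1) stop("sim_config: ", f, " must be in [0,1]")
  }
  if (cfg$within_subgroup_divergence > 0.25) {
    stop("sim_config: within_subgroup_divergence above 0.25 breaks the subgroup rule")
  }
  if (cfg$gene_spacing < 450L) {
    stop("sim_config: gene_spacing below 450 nt makes genes collide with leader windows")
  }
  if (cfg$v_exon_length %% 3L != 0L || cfg$leader_length %% 3L != 0L ||
      cfg$c_length %% 3L != 0L || cfg$j_length %% 3L != 0L) {
    stop("sim_config: translated segment lengths must be multiples of 3")
  }
  stopifnot(all(c("region", "subgroup", "n", "n_pseudo", "n_expressed") %in%
                  names(cfg$v_plan)))
  if (any(cfg$v_plan$n_pseudo > cfg$v_plan$n) ||
      any(cfg$v_plan$n_expressed > cfg$v_plan$n - cfg$v_plan$n_pseudo)) {
    stop("sim_config: pseudogene/expressed counts exceed gene counts")
  }
  class(cfg) <- "trb_sim_config"
  cfg
}

# Subgroup traversal order (V -> C direction) per region and unit. Novel
# subgroup 12 is placed after 13 in the reverse traversal so that, read in
# ascending genomic coordinates, its single gene appears first.
.unit_subgroup_order <- function(region, unit, subs_in_unit) {
  s <- sort(subs_in_unit)
  if (region == "TRB09" && unit == "rev" && all(c(12L, 13L) %in% s)) {
    s <- c(setdiff(s, c(12L, 13L)), 13L, 12L)
  }
  s
}

#' Simulate a dual-locus TRB genome with ground truth
#'
#' Builds subgroup ancestors from a root V gene, derives per-region gene
#' copies, plants pseudogene stops, leaders, J arrays with inverted identical
#' duplicates, a shared D core and 3/4-exon constant genes, and assembles the
#' three contigs. The same seed yields byte-identical output.
#'
#' @param config a [sim_config()] object.
#' @return list with elements `genome` (named character vector of contigs),
#'   `seeds` (seed tibble as in [read_seeds()]), `truth` (list of tibbles:
#'   `segments`, `expressed`, plus the ancestor table), `region_map`,
#'   `primers` (simulation [primer_set()]), and `config`.
#' @export
simulate_locus <- function(config = sim_config()) {
  stopifnot(inherits(config, "trb_sim_config"))
  set.seed(config$seed)
  plan <- config$v_plan
  regions <- unique(plan$region)
  subgroups <- sort(unique(plan$subgroup))
  anchored <- subgroups[subgroups <= 10L]
  novel <- subgroups[subgroups > 10L]

  Lv <- config$v_exon_length
  prot_primer <- seq_len(config$primer_length)

  # --- ancestors -----------------------------------------------------------
  root_v <- .random_cds(Lv %/% 3L)
  sub_anc <- list()
  for (s in anchored) {
    sub_anc[[as.character(s)]] <- .mutate_seq(root_v, rate = config$subgroup_divergence)
  }
  # novel subgroups: 11 and 13 are a diverged paralogue pair; the rest are
  # independent offshoots of the root.
  if (length(novel) > 0L) {
    novel_root <- .mutate_seq(root_v, rate = config$subgroup_divergence)
    for (s in novel) {
      if (s %in% c(11L, 13L)) {
        sub_anc[[as.character(s)]] <-
          .mutate_seq(novel_root, rate = config$novel_pair_divergence)
      } else {
        sub_anc[[as.character(s)]] <- .mutate_seq(root_v, rate = config$subgroup_divergence)
      }
    }
  }

  leader_anc <- lapply(setNames(nm = as.character(subgroups)), function(s) {
    paste0("ATG", .random_cds(config$leader_length %/% 3L - 1L))
  })

  # region-level ancestors: TRB01 carries the subgroup ancestor itself, the
  # duplicated region a diverged copy, the scaffold the TRB01 haplotype.
  reg_anc <- list()
  for (s in as.character(subgroups)) {
    reg_anc[[s]] <- list(
      TRB01 = sub_anc[[s]],
      TRB09 = .mutate_seq(sub_anc[[s]], rate = config$between_region_divergence,
                          protect = prot_primer),
      Scf   = sub_anc[[s]]
    )
  }

  # --- J, D, C -------------------------------------------------------------
  n_j_anc <- max(unlist(config$n_j))
  j_root <- .random_cds(config$j_length %/% 3L)
  j_anc <- vapply(seq_len(n_j_anc), function(i) .mutate_seq(j_root, rate = 0.12),
                  character(1))

  c_root <- .random_cds(config$c_length %/% 3L)
  n_aa_changes <- round(config$c_aa_divergence * (config$c_length %/% 3L))
  c_seq <- list(TRB01 = c_root,
                TRB09 = .diverge_codons_aa(c_root, n_aa_changes))
  c_exon_len <- list(TRB01 = c(170L, 180L, 160L),
                     TRB09 = c(120L, 150L, 140L, 100L))
  # scale the default splits if a non-default C length is requested
  for (r in names(c_exon_len)) {
    k <- c_exon_len[[r]]
    if (sum(k) != config$c_length) {
      k <- diff(round(seq(0, config$c_length, length.out = length(k) + 1L)))
      c_exon_len[[r]] <- as.integer(k)
    }
  }

  # --- per-gene sequences --------------------------------------------------
  genes <- list()   # rows accumulated into the truth table
  v_store <- list() # region -> subgroup -> member sequences (for scaffolding)
  for (r in regions) v_store[[r]] <- list()

  for (r in c("TRB01", "TRB09", "Scf")) {
    if (!r %in% regions) next
    pr <- plan[plan$region == r, , drop = FALSE]
    for (k in seq_len(nrow(pr))) {
      s <- as.character(pr$subgroup[k])
      n <- pr$n[k]
      members <- character(n)
      leaders <- character(n)
      for (i in seq_len(n)) {
        members[i] <- .mutate_seq(reg_anc[[s]][[r]],
                                  rate = config$within_subgroup_divergence,
                                  protect = prot_primer)
        leaders[i] <- paste0("ATG", .mutate_seq(
          substr(leader_anc[[s]], 4L, config$leader_length),
          rate = config$within_subgroup_divergence))
      }
      if (r == "Scf" && config$scaffold_identical_fraction > 0 &&
          !is.null(v_store[["TRB01"]][[s]])) {
        donor <- v_store[["TRB01"]][[s]]
        ok <- which(!vapply(donor$seq, has_internal_stop, logical(1)))
        n_copy <- min(floor(config$scaffold_identical_fraction * n),
                      length(ok), n - pr$n_pseudo[k])
        if (n_copy > 0L) {
          members[seq_len(n_copy)] <- donor$seq[ok[seq_len(n_copy)]]
          leaders[seq_len(n_copy)] <- donor$leader[ok[seq_len(n_copy)]]
        }
      }
      pseudo <- rep(FALSE, n)
      if (pr$n_pseudo[k] > 0L) {
        idx <- seq.int(n, by = -1L, length.out = pr$n_pseudo[k])
        pseudo[idx] <- TRUE
        for (i in idx) {
          ci <- sample(8:(Lv %/% 3L - 4L), 1L)
          substr(members[i], 3L * ci - 2L, 3L * ci) <- sample(.STOP_CODONS, 1L)
        }
      }
      expressed <- rep(FALSE, n)
      if (pr$n_expressed[k] > 0L) {
        ok <- which(!pseudo)
        expressed[ok[seq_len(pr$n_expressed[k])]] <- TRUE
      }
      v_store[[r]][[s]] <- tibble(
        member = seq_len(n), seq = members, leader = leaders,
        pseudo = pseudo, expressed = expressed
      )
    }
  }

  if (isTRUE(config$expressed_pseudogene)) {
    # one duplicated-region pseudogene with bona fide expressed transcripts
    st <- v_store[["TRB09"]][["3"]]
    cand <- which(st$pseudo)
    if (length(cand) > 0L) {
      st$expressed[cand[1L]] <- TRUE
      # expressed transcripts derive from an intact allele: store a stop-free
      # haplotype used only for amplicon generation
      fixed <- st$seq[cand[1L]]
      aa <- translate_nt(fixed)
      stop_at <- regexpr("*", substr(aa, 1, nchar(aa) - 1L), fixed = TRUE)
      ci <- as.integer(stop_at)
      substr(fixed, 3L * ci - 2L, 3L * ci) <- sample(.SENSE_CODONS, 1L)
      attr(st, "expressed_allele") <- setNames(fixed, cand[1L])
      v_store[["TRB09"]][["3"]] <- st
    }
  }

  # --- contig assembly -----------------------------------------------------
  contig_of <- c(TRB01 = "chr01", TRB09 = "chr09", Scf = "scaffold")
  genome <- list()
  seg_rows <- list()

  lone_forward <- list(TRB01 = TRUE, TRB09 = TRUE, Scf = FALSE)
  leaderless_tag <- c(region = "TRB09", subgroup = "13", member = "3")

  for (r in regions) {
    pr <- plan[plan$region == r, , drop = FALSE]
    subs <- pr$subgroup
    nf <- config$n_forward[[r]]
    # allocate genes to units: fill the forward unit subgroup-by-subgroup in
    # ascending subgroup order, remainder to the reverse unit
    alloc <- list(fwd = list(), rev = list())
    left <- nf
    for (s in sort(subs)) {
      n <- pr$n[pr$subgroup == s]
      take <- min(left, n)
      if (take > 0L) alloc$fwd[[as.character(s)]] <- seq_len(take)
      if (take < n) alloc$rev[[as.character(s)]] <- seq.int(take + 1L, n)
      left <- left - take
    }

    has_djc <- r %in% names(config$n_j$fwd)

    # J sequences per unit; reverse-unit copies of the listed indices are
    # sequence-identical to their forward counterparts (inverted duplicates)
    j_seq <- list(fwd = character(0), rev = character(0))
    if (has_djc) {
      n_f <- config$n_j$fwd[[r]]; n_r <- config$n_j$rev[[r]]
      j_seq$fwd <- vapply(seq_len(n_f), function(i)
        .mutate_seq(j_anc[i], rate = 0.05), character(1))
      j_seq$rev <- vapply(seq_len(n_r), function(i)
        .mutate_seq(j_anc[i], rate = 0.05), character(1))
      same <- intersect(config$j_inverted_identical[[r]], seq_len(min(n_f, n_r)))
      j_seq$rev[same] <- j_seq$fwd[same]
      if (r == "TRB09" && n_r >= 6L) j_seq$rev[5L] <- j_seq$rev[6L]
    }

    build_cassette <- function(gene) {
      # returns list(seq, elements = tibble(element, start, end)) in coding
      # orientation, 0-based half-open within the cassette
      if (gene$type == "V") {
        intron <- .make_intron(config$intron_length)
        if (gene$leaderless) {
          lead <- .scrub_atg(.random_dna(config$leader_length))
          seq <- paste0(lead, intron, gene$exon)
          el <- tibble(element = "exon",
                       start = nchar(lead) + nchar(intron),
                       end = nchar(seq))
        } else {
          seq <- paste0(gene$leader, intron, gene$exon)
          el <- tibble(element = c("leader", "exon"),
                       start = c(0L, nchar(gene$leader) + nchar(intron)),
                       end = c(nchar(gene$leader), nchar(seq)))
        }
        list(seq = seq, elements = el)
      } else if (gene$type == "C") {
        lens <- gene$exon_len
        parts <- character(0); el_s <- integer(0); el_e <- integer(0)
        off <- 0L; pos <- 1L
        for (i in seq_along(lens)) {
          ex <- substr(gene$exon, pos, pos + lens[i] - 1L)
          pos <- pos + lens[i]
          parts <- c(parts, ex)
          el_s <- c(el_s, off); off <- off + lens[i]; el_e <- c(el_e, off)
          if (i < length(lens)) {
            intr <- .make_intron(90L)
            parts <- c(parts, intr)
            off <- off + nchar(intr)
          }
        }
        list(seq = paste(parts, collapse = ""),
             elements = tibble(element = rep("exon", length(lens)),
                               start = el_s, end = el_e))
      } else {
        list(seq = gene$exon,
             elements = tibble(element = "exon", start = 0L, end = nchar(gene$exon)))
      }
    }

    # ordered cassette list left -> right on the forward strand
    cassettes <- list()
    push <- function(gene, strand, unit) {
      cassettes[[length(cassettes) + 1L]] <<-
        c(gene, list(strand = strand, unit = unit))
    }

    # reverse unit, ascending coordinates = reversed V->C traversal:
    # C, Jn..J1, D, V_last..V_first
    if (length(alloc$rev) > 0L || has_djc) {
      if (has_djc) {
        push(list(type = "C", gene_id = paste0(r, "_rev_C"), subgroup = NA,
                  exon = c_seq[[r]], exon_len = c_exon_len[[r]]), "-", "rev")
        for (j in rev(seq_along(j_seq$rev))) {
          push(list(type = "J", gene_id = paste0(r, "_rev_J", j), subgroup = NA,
                    exon = j_seq$rev[j]), "-", "rev")
        }
        push(list(type = "D", gene_id = paste0(r, "_rev_D"), subgroup = NA,
                  exon = config$d_core), "-", "rev")
      }
      ord <- .unit_subgroup_order(r, "rev", as.integer(names(alloc$rev)))
      trav <- list()
      for (s in ord) {
        st <- v_store[[r]][[as.character(s)]]
        for (i in alloc$rev[[as.character(s)]]) {
          trav[[length(trav) + 1L]] <- list(
            type = "V", gene_id = paste0(r, "_rev_V", s, "_", i),
            subgroup = s, exon = st$seq[i], leader = st$leader[i],
            pseudo = st$pseudo[i], expressed = st$expressed[i],
            leaderless = identical(unname(leaderless_tag),
                                   c(r, as.character(s), as.character(i)))
          )
        }
      }
      # lone opposite-strand V inside the reverse block (a translocated gene
      # retained on both paralogous regions)
      lone_idx <- if (lone_forward[[r]] && length(trav) >= 5L)
        ceiling(length(trav) / 2) else 0L
      for (i in rev(seq_along(trav))) {
        strand <- if (i == lone_idx) "+" else "-"
        push(trav[[i]], strand, "rev")
      }
    }

    # forward unit: V .. D .. J .. C in ascending coordinates
    ordf <- .unit_subgroup_order(r, "fwd", as.integer(names(alloc$fwd)))
    for (s in ordf) {
      st <- v_store[[r]][[as.character(s)]]
      for (i in alloc$fwd[[as.character(s)]]) {
        push(list(type = "V", gene_id = paste0(r, "_fwd_V", s, "_", i),
                  subgroup = s, exon = st$seq[i], leader = st$leader[i],
                  pseudo = st$pseudo[i], expressed = st$expressed[i],
                  leaderless = FALSE), "+", "fwd")
      }
    }
    if (has_djc) {
      push(list(type = "D", gene_id = paste0(r, "_fwd_D"), subgroup = NA,
                exon = config$d_core), "+", "fwd")
      for (j in seq_along(j_seq$fwd)) {
        push(list(type = "J", gene_id = paste0(r, "_fwd_J", j), subgroup = NA,
                  exon = j_seq$fwd[j]), "+", "fwd")
      }
      push(list(type = "C", gene_id = paste0(r, "_fwd_C"), subgroup = NA,
                exon = c_seq[[r]], exon_len = c_exon_len[[r]]), "+", "fwd")
    }

    # place cassettes
    contig_parts <- character(0)
    offset <- 0L
    add_spacer <- function() {
      sp <- .scrub_atg(.random_dna(config$gene_spacing))
      contig_parts <<- c(contig_parts, sp)
      offset <<- offset + nchar(sp)
    }
    add_spacer()
    for (cs in cassettes) {
      cas <- build_cassette(cs)
      M <- nchar(cas$seq)
      placed <- if (cs$strand == "+") cas$seq else revcomp(cas$seq)
      el <- cas$elements
      if (cs$strand == "+") {
        el$gstart <- offset + el$start
        el$gend <- offset + el$end
      } else {
        el$gstart <- offset + (M - el$end)
        el$gend <- offset + (M - el$start)
      }
      exons <- el[el$element == "exon", , drop = FALSE]
      lead <- el[el$element == "leader", , drop = FALSE]
      seg_rows[[length(seg_rows) + 1L]] <- tibble(
        gene_id = cs$gene_id, region = r, contig = contig_of[[r]],
        unit = cs$unit, segment_type = cs$type,
        subgroup = if (is.null(cs$subgroup) || is.na(cs$subgroup)) NA_integer_
                   else as.integer(cs$subgroup),
        start = min(exons$gstart), end = max(exons$gend),
        strand = cs$strand,
        exon_starts = list(sort(exons$gstart)),
        exon_ends = list(sort(exons$gend)),
        leader_start = if (nrow(lead)) lead$gstart else NA_integer_,
        leader_end = if (nrow(lead)) lead$gend else NA_integer_,
        nt = if (cs$type == "C") cs$exon else cs$exon,
        functionality = if (cs$type == "V" && isTRUE(cs$pseudo)) "P" else "ORF",
        expressed = isTRUE(cs$expressed)
      )
      contig_parts <- c(contig_parts, placed)
      offset <- offset + M
      add_spacer()
    }
    genome[[contig_of[[r]]]] <- paste(contig_parts, collapse = "")
  }

  segments <- dplyr::bind_rows(seg_rows)

  # --- seeds ---------------------------------------------------------------
  seed_rows <- list()
  for (s in anchored) {
    seed_rows[[length(seed_rows) + 1L]] <- tibble(
      seed_id = paste0("seedV", s), type = "V", subgroup = as.integer(s),
      gene = NA_character_, exon = NA_integer_, seq = sub_anc[[as.character(s)]])
  }
  for (s in novel) {
    seed_rows[[length(seed_rows) + 1L]] <- tibble(
      seed_id = paste0("seedVx", s), type = "V", subgroup = NA_integer_,
      gene = NA_character_, exon = NA_integer_, seq = sub_anc[[as.character(s)]])
  }
  for (i in seq_len(n_j_anc)) {
    seed_rows[[length(seed_rows) + 1L]] <- tibble(
      seed_id = paste0("seedJ", i), type = "J", subgroup = NA_integer_,
      gene = NA_character_, exon = NA_integer_, seq = j_anc[i])
  }
  seed_rows[[length(seed_rows) + 1L]] <- tibble(
    seed_id = "seedD", type = "D", subgroup = NA_integer_,
    gene = NA_character_, exon = NA_integer_, seq = config$d_core)
  for (r in intersect(c("TRB01", "TRB09"), regions)) {
    pos <- 1L
    for (i in seq_along(c_exon_len[[r]])) {
      ex <- substr(c_seq[[r]], pos, pos + c_exon_len[[r]][i] - 1L)
      pos <- pos + c_exon_len[[r]][i]
      seed_rows[[length(seed_rows) + 1L]] <- tibble(
        seed_id = paste0("seedC", sub("TRB", "", r), "_e", i), type = "C",
        subgroup = NA_integer_, gene = paste0("C", sub("TRB", "", r)),
        exon = i, seq = .mutate_seq(ex, rate = 0.02, coding = FALSE))
    }
  }
  seeds <- dplyr::bind_rows(seed_rows)

  # --- simulation primers --------------------------------------------------
  fwd_tail <- "ACACTCTTTCCCTACACGACGCTCTTCCGATCT"
  rev_tail <- "GTGACTGGAGTTCAGACGTGTGCTCTTCCGATCT"
  prim_rows <- list()
  for (s in subgroups) {
    prim_rows[[length(prim_rows) + 1L]] <- tibble(
      primer_id = paste0("V", s, ".F"), direction = "fwd",
      gs = substr(sub_anc[[as.character(s)]], 1L, config$primer_length),
      tail = fwd_tail)
  }
  for (r in intersect(c("TRB01", "TRB09"), regions)) {
    prim_rows[[length(prim_rows) + 1L]] <- tibble(
      primer_id = paste0(r, ".R"), direction = "rev",
      gs = revcomp(substr(c_seq[[r]], 41L, 60L)),
      tail = rev_tail)
  }
  primers <- primer_set(dplyr::bind_rows(prim_rows))

  expressed_allele <- attr(v_store[["TRB09"]][["3"]], "expressed_allele")

  list(
    genome = unlist(genome),
    seeds = seeds,
    truth = list(segments = segments,
                 expressed = segments$gene_id[segments$expressed],
                 expressed_allele = expressed_allele),
    region_map = tibble(contig = unname(contig_of[regions]),
                        region_label = regions,
                        scaffold = regions == "Scf"),
    primers = primers,
    config = config
  )
}

#' Simulate recombined paired-end amplicon reads
#'
#' Draws clonotypes from the expressed V genes of the simulated loci: a
#' same-unit J, geometric exonuclease trims, uniform-length non-templated
#' insertions around the D core, the regional constant-gene prefix, and
#' splits each transcript into inward-facing paired 250 nt reads with
#' per-base error. Transcripts are resampled until the anchored reading
#' frame is stop-free (the expressed repertoire is bona fide by
#' construction); the resample count is kept as an attribute.
#'
#' @param sim result of [simulate_locus()].
#' @param seed RNG seed for the amplicon stage (default derives from the
#'   locus seed).
#' @param regions which regions to amplify (default: both chromosomal ones).
#' @param error_rate overrides `sim$config$error_rate` when not `NULL`.
#' @return list with `pairs` (tibble `id`, `r1`, `q1`, `r2`, `q2`),
#'   `clonotypes` (per-clonotype truth: gene ids, trims, insertions, counts,
#'   transcript) and `n_resampled`.
#' @export
simulate_amplicons <- function(sim, seed = sim$config$seed + 1L,
                               regions = c("TRB01", "TRB09"),
                               error_rate = NULL) {
  set.seed(seed)
  cfg <- sim$config
  if (is.null(error_rate)) error_rate <- cfg$error_rate
  segs <- sim$truth$segments
  q_hi <- rawToChar(as.raw(33L + 37L))
  q_lo <- rawToChar(as.raw(33L + 12L))

  clono_rows <- list()
  pair_rows <- list()
  n_resampled <- 0L
  clono_n <- 0L

  draw_trim <- function() min(rgeom(1L, cfg$trim_geom_p), cfg$max_trim)

  for (r in intersect(regions, unique(segs$region))) {
    vset <- segs[segs$region == r & segs$segment_type == "V" & segs$expressed, ]
    if (nrow(vset) == 0L) next
    c_ref <- segs$nt[segs$region == r & segs$segment_type == "C" &
                       segs$unit == "fwd"][1]
    c_prefix <- substr(c_ref, 1L, cfg$c_amplicon_length)
    for (g in seq_len(nrow(vset))) {
      v <- vset[g, ]
      v_nt <- v$nt
      if (!is.null(sim$truth$expressed_allele) && v$functionality == "P" &&
          v$gene_id == paste0("TRB09_rev_V3_",
                              names(sim$truth$expressed_allele))) {
        v_nt <- unname(sim$truth$expressed_allele)
      }
      jset <- segs[segs$region == r & segs$segment_type == "J" &
                     segs$unit == v$unit, ]
      for (k in seq_len(cfg$clonotypes_per_gene)) {
        ok <- FALSE
        # N-insertion lengths are drawn once and kept: the in-frame
        # constraint is satisfied by resampling trims and content, so the
        # N-length marginals stay exactly uniform on 0..n_insertion_max
        n1l <- sample(0:cfg$n_insertion_max, 1L)
        n2l <- sample(0:cfg$n_insertion_max, 1L)
        for (try in seq_len(200L)) {
          j <- jset[sample(nrow(jset), 1L), ]
          v_trim <- draw_trim(); j_trim <- draw_trim()
          d5 <- min(rgeom(1L, cfg$trim_geom_p), 3L)
          d3 <- min(rgeom(1L, cfg$trim_geom_p), 3L)
          n1 <- if (n1l) .random_dna(n1l) else ""
          n2 <- if (n2l) .random_dna(n2l) else ""
          d_rem <- substr(cfg$d_core, d5 + 1L, nchar(cfg$d_core) - d3)
          tx <- paste0(substr(v_nt, 1L, nchar(v_nt) - v_trim), n1, d_rem, n2,
                       substr(j$nt, j_trim + 1L, nchar(j$nt)), c_prefix)
          if (nchar(tx) %% 3L == 0L &&
              !grepl("*", translate_nt(tx), fixed = TRUE)) { ok <- TRUE; break }
          n_resampled <- n_resampled + 1L
        }
        if (!ok) next
        clono_n <- clono_n + 1L
        cid <- sprintf("clono_%04d", clono_n)
        # germline J genes indistinguishable from the one used
        j_ident <- jset$gene_id[jset$nt == j$nt]
        clono_rows[[clono_n]] <- tibble(
          clonotype_id = cid, region = r, v_gene = v$gene_id,
          j_gene = j$gene_id, j_identical = paste(sort(j_ident), collapse = ","),
          v_trim = v_trim, j_trim = j_trim, d5_trim = d5, d3_trim = d3,
          n1 = n1, n2 = n2, count = cfg$reads_per_clonotype, transcript = tx)

        L <- nchar(tx)
        rl <- cfg$read_length
        r1t <- substr(paste0(tx, revcomp(sim$primers$rev$tail[1]),
                             strrep("A", rl)), 1L, rl)
        r2t <- substr(paste0(revcomp(tx), revcomp(sim$primers$fwd$tail[1]),
                             strrep("A", rl)), 1L, rl)
        for (i in seq_len(cfg$reads_per_clonotype)) {
          seqs <- c(r1t, r2t); quals <- character(2)
          for (m in 1:2) {
            v1 <- strsplit(seqs[m], "", fixed = TRUE)[[1]]
            err <- which(runif(length(v1)) < error_rate)
            qv <- rep(q_hi, length(v1))
            for (p in err) {
              v1[p] <- sample(setdiff(c("A", "C", "G", "T"), v1[p]), 1L)
              qv[p] <- q_lo
            }
            seqs[m] <- paste(v1, collapse = "")
            quals[m] <- paste(qv, collapse = "")
          }
          pair_rows[[length(pair_rows) + 1L]] <- tibble(
            id = sprintf("%s_read%03d", cid, i),
            r1 = seqs[1], q1 = quals[1], r2 = seqs[2], q2 = quals[2])
        }
      }
    }
  }
  out <- list(pairs = dplyr::bind_rows(pair_rows),
              clonotypes = dplyr::bind_rows(clono_rows),
              n_resampled = n_resampled)
  out
}
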