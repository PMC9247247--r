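seed_tbl <- function(ids, types, seqs, subgroups = NA_integer_) {
  tibble::tibble(seed_id = ids, type = types,
                 subgroup = rep_len(subgroups, length(ids)),
                 gene = NA_character_, exon = NA_integer_, seq = seqs)
}

test_that("an exact seed copy on the reverse strand is found with identity 1", {
  withr::with_seed(21, {
    v1 <- rand_cds(60)  # 180 nt
    genome <- c(ctg = paste0(rand_dna(400), revcomp(v1), rand_dna(400)))
    seeds <- seed_tbl("V1seed", "V", v1, 1L)
    hits <- suppressWarnings(find_candidates(genome, seeds))
    expect_equal(nrow(hits), 1L)
    expect_identical(hits$strand, "-")
    expect_equal(hits$identity, 1)
    expect_identical(hits$nt, v1)
    expect_equal(hits$start, 400)
    expect_equal(hits$end, 400 + 180)
  })
})

test_that("a genome without similarity to any seed yields no candidates", {
  withr::with_seed(22, {
    genome <- c(ctg = rand_dna(2000))
    seeds <- seed_tbl("V1seed", "V", rand_cds(60), 1L)
    # a random 180-mer has no 11-mer diagonal support in 2 kb
    expect_equal(nrow(suppressWarnings(find_candidates(genome, seeds))), 0L)
  })
})

test_that("empty inputs are errors and missing seed types warn", {
  withr::with_seed(23, {
    genome <- c(ctg = rand_dna(500))
    expect_error(find_candidates(character(0), seed_tbl("s", "V", "ACGT")),
                 "genome")
    expect_error(read_seeds(Biostrings::DNAStringSet()), "empty")
    expect_warning(find_candidates(genome, seed_tbl("s", "V", rand_cds(40), 1L)),
                   "no seeds for segment type")
  })
})

test_that("round trip on a simulated locus recovers segments, strands and stops", {
  sim <- tiny_sim(); ann <- tiny_ann()
  tv <- sim$truth$segments
  av <- ann$segments
  key_t <- paste(tv$contig, tv$start, tv$end, tv$strand)
  key_a <- paste(av$contig, av$start, av$end, av$strand)
  expect_gte(mean(key_t %in% key_a), 0.95)
  # functionality labels match the planted stop codons exactly at
  # coordinate-matched V genes
  m <- merge(tv[tv$segment_type == "V", c("contig", "start", "functionality")],
             av[av$segment_type == "V", c("contig", "start", "functionality")],
             by = c("contig", "start"))
  expect_identical(m$functionality.x, m$functionality.y)
  # unit assignment matches, including the lone opposite-strand V inside the
  # reverse unit
  mu <- merge(tv[, c("contig", "start", "unit", "strand")],
              av[, c("contig", "start", "unit", "strand")],
              by = c("contig", "start"))
  expect_identical(mu$unit.x, mu$unit.y)
  expect_true(any(mu$unit.x == "rev" & mu$strand.x == "+"))
})

test_that("subgroup recovery agrees with planted partition and census counts", {
  sim <- tiny_sim(); ann <- tiny_ann()
  tv <- sim$truth$segments; av <- ann$segments
  m <- merge(tv[tv$segment_type == "V", c("contig", "start", "subgroup")],
             av[av$segment_type == "V", c("contig", "start", "subgroup")],
             by = c("contig", "start"))
  # same planted subgroup <=> same recovered subgroup (label-free partition)
  f1 <- as.integer(factor(m$subgroup.x))
  f2 <- as.integer(factor(m$subgroup.y))
  expect_true(all(outer(f1, f1, "==") == outer(f2, f2, "==")))
  # anchored subgroups keep the seed's number
  anchored <- m$subgroup.x <= 10
  expect_identical(m$subgroup.y[anchored], m$subgroup.x[anchored])
})

test_that("functionality calling follows the internal stop rule", {
  withr::with_seed(24, {
    v <- rand_cds(100)
    expect_identical(as.character(call_functionality(v)), "ORF")
    substr(v, 88, 90) <- "TAA"  # internal stop at codon 30
    expect_identical(as.character(call_functionality(v)), "P")
    short <- call_functionality("AC")
    expect_identical(as.character(short), "P")
    expect_identical(attr(short, "reason"), "frame-disrupted")
  })
})

test_that("naming follows the two-orientation scheme", {
  seg <- tibble::tibble(
    segment_type = c("V", "V", "D", "J", "J", "C"),
    start = c(100L, 600L, 1100L, 1600L, 2100L, 2600L),
    end = c(400L, 900L, 1112L, 1650L, 2150L, 3100L),
    strand = "+", unit = "fwd",
    subgroup = c(3L, 3L, NA, NA, NA, NA),
    functionality = c("ORF", "ORF", "ORF", "ORF", "ORF", "ORF"),
    gene_id = letters[1:6]
  )
  named <- assign_names(seg, "TRB09")
  expect_identical(named$name,
                   c("TRB09V3-1", "TRB09V3-2", "TRB09D", "TRB09J1", "TRB09J2",
                     "TRB09C"))
  # same genes in the reverse unit: numbering restarts, R inserted, and the
  # V -> C direction runs right to left
  segr <- seg; segr$strand <- "-"; segr$unit <- "rev"
  segr$start <- rev(seg$start); segr$end <- rev(seg$end)
  namedr <- assign_names(segr, "TRB09")
  expect_identical(sort(namedr$name),
                   sort(c("TRB09RV3-1", "TRB09RV3-2", "TRB09RD", "TRB09RJ1",
                          "TRB09RJ2", "TRB09RC")))
  expect_identical(namedr$name[namedr$start == 2600L], "TRB09RV3-1")
  # pseudogene V carries the _P extension
  segp <- seg; segp$functionality[2] <- "P"
  expect_identical(assign_names(segp, "TRB09")$name[2], "TRB09V3-2_P")
  # scaffold variant uses S ordinals
  expect_identical(assign_names(seg, "TRB01", scaffold = TRUE)$name[1],
                   "Scf.TRBV3S1")
  # deterministic: renaming after a no-op re-sort is byte-identical
  expect_identical(assign_names(named, "TRB09")$name, named$name)
  # unclassified V is an error
  segna <- seg; segna$subgroup[1] <- NA
  expect_error(assign_names(segna, "TRB09"), "unclassified")
})

test_that("leader recovery finds planted leaders and respects its policy", {
  sim <- tiny_sim(); ann <- tiny_ann()
  tv <- sim$truth$segments; av <- ann$segments
  m <- merge(tv[tv$segment_type == "V",
                c("contig", "start", "leader_start", "leader_end", "functionality")],
             av[av$segment_type == "V",
                c("contig", "start", "leader_start", "leader_end")],
             by = c("contig", "start"), suffixes = c(".t", ".a"))
  planted <- !is.na(m$leader_start.t) & m$functionality != "P"
  expect_true(all(m$leader_start.t[planted] == m$leader_start.a[planted] &
                    m$leader_end.t[planted] == m$leader_end.a[planted]))
  withr::with_seed(25, {
    v <- rand_cds(60)
    # no upstream ATG -> absent
    win <- paste0(gsub("ATG|CAT", "ACC", rand_dna(300)), "AG")
    contig <- paste0(win, v)
    expect_null(find_leader(contig, nchar(win), nchar(win) + 180, "+", v,
                            window = nchar(win)))
    # two candidate leaders: the longer stop-free exon wins
    lead_long <- paste0("ATG", rand_cds(15))             # 48 nt
    intron <- paste0("GT", paste(sample(c("A", "C", "T"), 66, TRUE), collapse = ""), "AG")
    spacer <- gsub("ATG|CAT", "ACC", rand_dna(230))
    contig2 <- paste0(spacer, lead_long, intron, v)
    got <- find_leader(contig2, nchar(spacer) + 48 + 70, 9999, "+", v,
                       window = 300L)
    expect_identical(got$exon_seq, lead_long)
    # truncated window warns and returns absent
    expect_warning(out <- find_leader(contig2, 100, 300, "+", v, window = 400L),
                   "truncated")
    expect_null(out)
  })
})
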