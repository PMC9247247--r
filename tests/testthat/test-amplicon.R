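mk_pairs <- function(r1, r2, q1 = NULL, q2 = NULL) {
  tibble::tibble(
    id = sprintf("p%02d", seq_along(r1)),
    r1 = r1, q1 = if (is.null(q1)) strrep("F", nchar(r1)) else q1,
    r2 = r2, q2 = if (is.null(q2)) strrep("F", nchar(r2)) else q2)
}

test_that("quality trimming removes low-quality tails and adapter read-through", {
  withr::with_seed(51, {
    # all high quality: unchanged
    p <- mk_pairs(rand_dna(100), rand_dna(100))
    out <- quality_trim(p)
    expect_identical(out$r1, p$r1)
    expect_identical(attr(out, "n_dropped"), 0L)
    # 30 nt Q2 tail: removed
    r <- rand_dna(100)
    p2 <- mk_pairs(r, rand_dna(100),
                   q1 = paste0(strrep("F", 70), strrep("#", 30)))
    out2 <- quality_trim(p2)
    expect_identical(out2$r1, substr(r, 1, 70))
    # pairs below the length floor are dropped
    p3 <- mk_pairs(rand_dna(30), rand_dna(100))
    out3 <- quality_trim(p3)
    expect_identical(nrow(out3), 0L)
    expect_identical(attr(out3, "n_dropped"), 1L)
    # adapter read-through: 150 nt insert in 200 nt reads
    insert <- rand_dna(150)
    adA <- "AGATCGGAAGAGCACACGTCTGAACTCCAGTCACAAAAAAAAAAAAAAAA"
    adB <- "AGATCGGAAGAGCGTCGTGTAGGGAAAGAGTGTAAAAAAAAAAAAAAAAA"
    p4 <- mk_pairs(paste0(insert, adA), paste0(revcomp(insert), adB))
    out4 <- quality_trim(p4)
    expect_identical(out4$r1, insert)
    expect_identical(out4$r2, revcomp(insert))
  })
})

test_that("desynchronized FASTQ pairs are rejected with the offender named", {
  withr::with_seed(52, {
    d <- withr::local_tempdir()
    s1 <- Biostrings::DNAStringSet(c(x1 = "ACGTACGTAC", x2 = "ACGTACGTAC"))
    s2 <- Biostrings::DNAStringSet(c(x1 = "ACGTACGTAC", y2 = "ACGTACGTAC"))
    q <- Biostrings::BStringSet(c("FFFFFFFFFF", "FFFFFFFFFF"))
    f1 <- file.path(d, "a_R1.fastq"); f2 <- file.path(d, "a_R2.fastq")
    Biostrings::writeXStringSet(s1, f1, format = "fastq", qualities = q)
    Biostrings::writeXStringSet(s2, f2, format = "fastq", qualities = q)
    expect_error(read_fastq_pairs(f1, f2), "record 2.*x2|x2.*record 2")
    # round trip of a healthy pair of files
    p <- mk_pairs(c("ACGTAC", "GGGTTT"), c("TTTAAA", "CCCAAA"))
    pref <- file.path(d, "ok")
    write_fastq_pairs(p, pref)
    back <- read_fastq_pairs(paste0(pref, "_R1.fastq"), paste0(pref, "_R2.fastq"))
    expect_identical(back$r1, p$r1)
    expect_identical(back$q2, p$q2)
  })
})

test_that("demultiplexing matches primer panels IUPAC-aware and partitions input", {
  ps <- trb_primers()
  withr::with_seed(53, {
    tail1 <- rand_dna(120); tail2 <- rand_dna(120)
    # exact V8 forward + TRB09 reverse -> that bin
    p <- mk_pairs(paste0("GTTGCGTTTCGTCAGTCTCC", tail1),
                  paste0("GACTTGCCAGAAGACCGTGA", tail2))
    dm <- demultiplex(p, ps)
    expect_identical(names(dm$bins), "V8.F|TRB09.R")
    # IUPAC S and M positions accept C/G and A/C respectively
    v3 <- "AGTTCAACTSAMCTGCAGMC"
    read_g <- chartr("SM", "GA", v3); read_c <- chartr("SM", "CC", v3)
    p2 <- mk_pairs(paste0(c(read_g, read_c), tail1),
                   rep(paste0("GTTGTCGGTCCCAACTCCAT", tail2), 2))
    dm2 <- demultiplex(p2, ps)
    expect_identical(names(dm2$bins), "V3.F|TRB01.R")
    expect_identical(nrow(dm2$bins[[1]]), 2L)
    # shuffled read: undetermined
    p3 <- mk_pairs(rand_dna(140), rand_dna(140))
    dm3 <- demultiplex(p3, ps)
    expect_identical(nrow(dm3$undetermined), 1L)
    # a read matching two forward primers equally is not guessed
    amb <- primer_set(tibble::tibble(
      primer_id = c("f1", "f2", "r1"), direction = c("fwd", "fwd", "rev"),
      gs = c("AAAATTTT", "AAAATTTA", "GGGGCCCC"), tail = ""))
    p4 <- mk_pairs(paste0("AAAATTTC", rand_dna(50)),
                   paste0("GGGGCCCC", rand_dna(50)))
    dm4 <- demultiplex(p4, amb, max_mismatch = 1)
    expect_identical(nrow(dm4$undetermined), 1L)
    # partition: bins + undetermined account for every read exactly once
    mix <- mk_pairs(c(paste0("GTTGCGTTTCGTCAGTCTCC", tail1), rand_dna(80),
                      paste0("GGTCTTGTTGAGGGGAGTGA", tail1)),
                    c(paste0("GACTTGCCAGAAGACCGTGA", tail2), rand_dna(80),
                      paste0("GTTGTCGGTCCCAACTCCAT", tail2)))
    dmm <- demultiplex(mix, ps)
    got_ids <- c(unlist(lapply(dmm$bins, `[[`, "id")), dmm$undetermined$id)
    expect_setequal(got_ids, mix$id)
    expect_identical(length(got_ids), nrow(mix))
  })
})

test_that("pair merging reproduces inserts and resolves conflicts by quality", {
  withr::with_seed(54, {
    insert <- rand_dna(420)
    p <- mk_pairs(substr(insert, 1, 250), revcomp(substr(insert, 171, 420)))
    m <- merge_pairs(p)
    expect_identical(nchar(m$sequence), 420L)  # 250 + 250 - 80 overlap
    expect_identical(m$sequence, insert)
    # disagreement in the overlap: the higher-quality base wins
    r1 <- substr(insert, 1, 250)
    bad <- r1
    substr(bad, 200, 200) <- setdiff(c("A", "C", "G", "T"),
                                     substr(insert, 200, 200))[1]
    q1 <- strrep("F", 250)  # Q37
    q2 <- strrep("+", 250)  # Q10
    pq <- mk_pairs(bad, revcomp(substr(insert, 171, 420)), q1 = q1, q2 = q2)
    mq <- merge_pairs(pq)
    expect_identical(substr(mq$sequence, 200, 200), substr(bad, 200, 200))
    # and the other way around
    pq2 <- mk_pairs(bad, revcomp(substr(insert, 171, 420)),
                    q1 = strrep("+", 250), q2 = strrep("F", 250))
    mq2 <- merge_pairs(pq2)
    expect_identical(mq2$sequence, insert)
    # unmergeable pairs are dropped and counted
    p0 <- mk_pairs(rand_dna(60), rand_dna(60))
    m0 <- merge_pairs(p0, min_overlap = 20)
    expect_identical(nrow(m0), 0L)
    expect_identical(attr(m0, "n_unmerged"), 1L)
  })
})

test_that("merge rate on simulated amplicons is near-complete at low error", {
  sim <- tiny_sim()
  amp <- simulate_amplicons(sim, seed = 77, error_rate = 0.001)
  m <- merge_pairs(amp$pairs)
  rate <- nrow(m) / nrow(amp$pairs)
  expect_gte(rate, 0.99)
})

test_that("collapsing counts unique fragments and conserves reads", {
  col <- collapse_reads(c("AAA", "AAA", "AAT"), "V9")
  expect_identical(col$sequence, c("AAA", "AAT"))
  expect_identical(col$count, c(2L, 1L))
  expect_identical(col$sequence_id, c("V9_1-2", "V9_2-1"))
  expect_identical(nrow(collapse_reads(character(0))), 0L)
  withr::with_seed(55, {
    seqs <- sample(replicate(40, rand_dna(12)), 3000, replace = TRUE)
    col2 <- collapse_reads(seqs)
    expect_identical(sum(col2$count), length(seqs))
    # independent recount via run-length encoding on the sorted multiset
    r <- rle(sort(seqs))
    expect_identical(stats::setNames(col2$count[order(col2$sequence)], NULL),
                     r$lengths)
    # sorted by descending count then sequence
    expect_true(all(diff(col2$count) <= 0))
  })
})

test_that("ORF filtering anchors the frame at the constant gene", {
  withr::with_seed(56, {
    c_ref <- rand_cds(40)
    c_refs <- c(TRB09 = c_ref)
    v_part <- rand_cds(30)
    good <- paste0(v_part, substr(c_ref, 1, 36))
    col <- collapse_reads(good)
    out <- orf_filter(col, c_refs)
    expect_true(out$orf_ok)
    # out-of-frame join (5' length not a multiple of 3): the frame anchored
    # at the constant gene reads a stop upstream of the anchor
    shift <- paste0("GGTAA", strrep("GCA", 12), substr(c_ref, 1, 36))
    out2 <- orf_filter(collapse_reads(shift), c_refs)
    expect_false(out2$orf_ok)
    expect_identical(out2$orf_reason, "internal_stop")
    # no constant anchor at all
    out3 <- orf_filter(collapse_reads(rand_dna(90)), c_refs)
    expect_false(out3$orf_ok)
    expect_identical(out3$orf_reason, "no_c_anchor")
  })
})

test_that("germline assignment finds exact matches, ambiguity sets and novel sequences", {
  sim <- tiny_sim(); ann <- tiny_ann()
  rep <- memo("tiny_rep", {
    amp <- simulate_amplicons(sim, error_rate = 0)
    dm <- demultiplex(quality_trim(amp$pairs), sim$primers)
    segs <- ann$segments
    c_refs <- stats::setNames(
      segs$nt[segs$segment_type == "C" & segs$unit == "fwd"],
      segs$region_label[segs$segment_type == "C" & segs$unit == "fwd"])
    col <- dplyr::bind_rows(lapply(names(dm$bins), function(bn) {
      mg <- merge_pairs(dm$bins[[bn]])
      collapse_reads(mg$sequence, gsub("\\.F[0-9]*\\|", ".", sub("\\.R$", "", bn)))
    }))
    col <- orf_filter(col, c_refs)
    list(clono = assign_germline(col, ann), amp = amp)
  })
  clono <- rep$clono
  expect_true(all(!clono$novel))
  expect_true(all(clono$orf_ok))
  # every transcript's true V gene is inside the called ambiguity set
  nm <- truth_name_map(sim, ann)
  truth_by_tx <- stats::setNames(as.character(nm[rep$amp$clonotypes$v_gene]),
                                 rep$amp$clonotypes$transcript)
  hit <- vapply(seq_len(nrow(clono)), function(i) {
    tr <- truth_by_tx[[clono$sequence[i]]]
    !is.null(tr) && tr %in% clono$v_call_list[[i]]
  }, logical(1))
  expect_true(all(hit))
  # c_call matches the transcript's region
  reg <- stats::setNames(rep$amp$clonotypes$region, rep$amp$clonotypes$transcript)
  expect_identical(clono$c_call, unname(reg[clono$sequence]))
  # one mismatch away from the nearest gene -> novel
  seq1 <- clono$sequence[1]
  mut <- seq1
  substr(mut, 40, 40) <- setdiff(c("A", "C", "G", "T"), substr(seq1, 40, 40))[1]
  col1 <- clono[1, c("sequence_id", "sequence", "count", "orf_ok", "c_pos")]
  col1$sequence <- mut
  out <- assign_germline(col1, ann)
  expect_true(out$novel)
})

test_that("identical germline copies produce multi-member v_call sets", {
  ann <- tiny_ann()
  segs <- ann$segments
  # duplicate a V gene under a second name to force an ambiguity set
  vrow <- which(segs$segment_type == "V")[1]
  dup <- segs[vrow, ]
  dup$name <- "DUPLICATE-V"; dup$start <- dup$start + 1e6
  ann2 <- ann; ann2$segments <- dplyr::bind_rows(segs, dup)
  c_ref <- segs$nt[segs$segment_type == "C" & segs$unit == "fwd"][1]
  tx <- paste0(segs$nt[vrow], "GGTT", substr(c_ref, 1, 40))
  col <- collapse_reads(tx)
  out <- assign_germline(col, ann2)
  expect_gte(length(out$v_call_list[[1]]), 2L)
  expect_true("DUPLICATE-V" %in% out$v_call_list[[1]])
})

test_that("expressed support marks F at the read-support threshold", {
  sim <- tiny_sim(); ann <- tiny_ann()
  segs <- ann$segments
  v <- segs[segs$segment_type == "V" & segs$functionality == "ORF", ][1, ]
  c_ref <- segs$nt[segs$segment_type == "C" & segs$unit == "fwd" &
                     segs$region_label == v$region_label][1]
  tx <- paste0(v$nt, "GGG", substr(c_ref, 1, 42))  # in-frame join
  mk_clono <- function(count) {
    out <- assign_germline(orf_filter(collapse_reads(rep(tx, count)),
                                      stats::setNames(c_ref, v$region_label)), ann)
    out
  }
  hi <- mark_expressed(ann, mk_clono(58))
  expect_identical(
    hi$annotation$segments$functionality[hi$annotation$segments$name == v$name],
    "F")
  lo <- mark_expressed(ann, mk_clono(3))
  expect_identical(
    lo$annotation$segments$functionality[lo$annotation$segments$name == v$name],
    "ORF")
  # a pseudogene matched by bona fide transcripts is a status conflict
  p <- segs[segs$segment_type == "V" & segs$functionality == "P", ][1, ]
  aa <- translate_nt(p$nt)
  ci <- regexpr("*", aa, fixed = TRUE)[1]
  fixed <- p$nt
  substr(fixed, 3 * ci - 2, 3 * ci) <- "GGA"
  ctx <- paste0(fixed, "GG", substr(c_ref, 1, 40))
  # transcripts matching the gene over its covered portion minus the stop:
  # use the intact allele so the prefix matches up to the planted stop codon
  clono_p <- tibble::tibble(
    sequence_id = "x_1-30", sequence = ctx, count = 30L, orf_ok = TRUE,
    v_call = p$name, v_call_list = list(p$name), novel = FALSE,
    c_call = p$region_label, c_pos = nchar(fixed) + 3L)
  conf <- mark_expressed(ann, clono_p)
  expect_identical(conf$conflicts$name, p$name)
  expect_identical(
    conf$annotation$segments$functionality[conf$annotation$segments$name == p$name],
    "P")
})
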