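test_that("barcode grouping keeps molecules together and splits on large gaps", {
  reads <- dplyr::bind_rows(
    make_read("a1", 1000, "ACGT", barcode = "X"),
    make_read("a2", 2000, "ACGT", barcode = "X"),
    make_read("a3", 3000, "ACGT", barcode = "X")
  )
  g <- group_fragments(reads, max_gap = 50000)
  expect_equal(dplyr::n_distinct(g$fragment_id), 1)

  far <- dplyr::bind_rows(
    make_read("b1", 1000, "ACGT", barcode = "X"),
    make_read("b2", 201000, "ACGT", barcode = "X")
  )
  g <- group_fragments(far, max_gap = 50000)
  expect_equal(dplyr::n_distinct(g$fragment_id), 2)

  ## barcode-less reads become singletons
  mixed <- dplyr::bind_rows(
    make_read("c1", 10, "ACGT"),
    make_read("c2", 20, "ACGT")
  )
  g <- group_fragments(mixed, max_gap = 50000)
  expect_equal(dplyr::n_distinct(g$fragment_id), 2)
})

test_that("grouping matches a brute-force oracle on randomized barcoded reads", {
  set.seed(101)
  for (rep in 1:20) {
    n <- 40
    reads <- dplyr::bind_rows(lapply(seq_len(n), function(i) {
      make_read(paste0("r", i), sample.int(400000, 1),
        strrep("A", 100),
        barcode = sample(paste0("B", 1:8), 1)
      )
    }))
    max_gap <- sample(c(5000, 20000, 50000), 1)
    g <- group_fragments(reads, max_gap = max_gap)
    oracle <- oracle_group_fragments(reads, max_gap)
    expect_equal(dplyr::n_distinct(g$fragment_id), length(oracle))
    ## identical partition: each oracle group maps to exactly one fragment_id
    for (grp in oracle) {
      expect_equal(dplyr::n_distinct(g$fragment_id[grp]), 1)
    }
  }
})

test_that("haplotype voting follows allele matches, ties and mate dedup rules", {
  ref <- strrep("A", 200)
  hets <- make_hets(c(50, 120), h1 = c("C", "G"), h2 = c("T", "A"))
  ## both hets matched to h1 alleles (50 bp reads: one het each)
  reads <- dplyr::bind_rows(
    make_read("p1", 40, paste0(strrep("A", 10), "C", strrep("A", 39)), barcode = "X"),
    make_read("p2", 100, paste0(strrep("A", 20), "G", strrep("A", 29)), barcode = "X")
  )
  fr <- assign_haplotypes(group_fragments(reads, 50000), hets)
  expect_equal(fr$haplotype, "H1")
  expect_equal(fr$votes_h1, 2L)
  expect_equal(fr$votes_h2, 0L)

  ## one vote each way -> unassigned, never random
  reads2 <- dplyr::bind_rows(
    make_read("p1", 40, paste0(strrep("A", 10), "C", strrep("A", 39)), barcode = "X"),
    make_read("p2", 100, paste0(strrep("A", 20), "A", strrep("A", 29)), barcode = "X")
  )
  fr2 <- assign_haplotypes(group_fragments(reads2, 50000), hets)
  expect_equal(fr2$haplotype, "unassigned")

  ## overlapping mates at one het count once; higher base quality wins
  r1 <- make_read("m", 40, paste0(strrep("A", 10), "C", strrep("A", 39)),
    barcode = "X", qual = paste0(strrep("J", 10), "5", strrep("J", 39))
  ) ## bq 20 at het
  r2 <- make_read("m", 45, paste0(strrep("A", 5), "T", strrep("A", 44)),
    barcode = "X", is_read1 = FALSE
  ) ## bq 41 at het
  fr3 <- assign_haplotypes(group_fragments(dplyr::bind_rows(r1, r2), 50000), hets)
  expect_equal(fr3$haplotype, "H2") ## the T observation (bq 41) wins
  expect_equal(fr3$votes_h1 + fr3$votes_h2, 1L)

  ## votes below the base-quality floor are discarded
  low <- make_read("l", 40, paste0(strrep("A", 10), "C", strrep("A", 39)),
    barcode = "Y", qual = paste0(strrep("J", 10), "+", strrep("J", 39))
  ) ## bq 10
  fr4 <- assign_haplotypes(group_fragments(low, 50000), hets)
  expect_equal(fr4$haplotype, "unassigned")
  expect_equal(fr4$votes_h1 + fr4$votes_h2, 0L)
})

test_that("randomized fragment assignment equals a per-het vote recount", {
  set.seed(202)
  L <- 50000L
  hets <- make_hets(sort(sample.int(L - 1, 50)),
    h1 = sample(c("C", "G"), 50, TRUE),
    h2 = sample(c("T", "A"), 50, TRUE)
  )
  for (rep in 1:15) {
    n_reads <- sample(3:8, 1)
    start <- sort(sample.int(L - 200, n_reads))
    reads <- dplyr::bind_rows(lapply(seq_len(n_reads), function(i) {
      seq <- paste(sample(c("A", "C", "G", "T"), 150, TRUE), collapse = "")
      make_read(paste0("r", rep, "_", i), start[i], seq, barcode = "BC")
    }))
    grouped <- group_fragments(reads, max_gap = L)
    fr <- assign_haplotypes(grouped, hets)
    oracle <- oracle_fragment_vote(grouped, hets)
    expect_equal(fr$votes_h1, oracle$votes_h1)
    expect_equal(fr$votes_h2, oracle$votes_h2)
    expect_equal(fr$haplotype, oracle$haplotype)
  }
})

test_that("site summaries conserve depth across haplotypes and honor modes", {
  fx <- small_sim()
  g <- fx$genome
  frag <- build_fragments(fx$sim$reads, g$truth$hets, mode = "full")
  pos <- g$truth$mosaic$pos
  obs <- site_phase_summary(frag$reads, pos, g$reference,
    fragments = frag$fragments, candidate_allele = g$truth$mosaic$alt
  )
  expect_equal(obs$depth, obs$n_h1 + obs$n_h2 + obs$n_un)
  expect_equal(obs$maf, ifelse(obs$depth > 0, obs$alt_count / obs$depth, 0))
  ## discordant reads are exactly the assigned candidate reads
  expect_equal(obs$discordant_count, obs$alt_h1 + obs$alt_h2)

  ## no_phasing: everything unassigned, no discordant evidence
  frag_np <- build_fragments(fx$sim$reads, g$truth$hets, mode = "no_phasing")
  obs_np <- site_phase_summary(frag_np$reads, pos, g$reference,
    fragments = frag_np$fragments, candidate_allele = g$truth$mosaic$alt,
    mode = "no_phasing"
  )
  expect_true(all(obs_np$phased_fraction == 0))
  expect_true(all(obs_np$discordant_count == 0))
  expect_equal(obs_np$depth, obs$depth)
  expect_equal(obs_np$alt_count, obs$alt_count)

  ## mode ordering of phased fractions: 0 <= short_only <= full
  frag_so <- build_fragments(fx$sim$reads, g$truth$hets, mode = "short_only")
  obs_so <- site_phase_summary(frag_so$reads, pos, g$reference,
    fragments = frag_so$fragments, candidate_allele = g$truth$mosaic$alt,
    mode = "short_only"
  )
  expect_true(all(obs_so$phased_fraction <= obs$phased_fraction + 1e-9))
  expect_true(mean(obs_so$phased_fraction) < mean(obs$phased_fraction))
})

test_that("random pileup haplotype counts match a read-by-read recount", {
  fx <- small_sim()
  g <- fx$genome
  frag <- build_fragments(fx$sim$reads, g$truth$hets, mode = "full")
  frag_hap <- setNames(
    as.list(frag$fragments$haplotype), frag$fragments$fragment_id
  )
  set.seed(7)
  pos <- sample.int(fx$cfg$region_length - 1L, 40)
  obs <- site_phase_summary(frag$reads, pos, g$reference,
    fragments = frag$fragments
  )
  for (i in seq_along(pos)) {
    oracle <- oracle_site_counts(frag$reads, pos[i], frag_hap)
    expect_equal(obs$depth[i], sum(oracle$counts))
    expect_equal(
      c(obs$n_h1[i], obs$n_h2[i], obs$n_un[i]),
      c(
        sum(oracle$by_hap$H1), sum(oracle$by_hap$H2),
        sum(oracle$by_hap$unassigned)
      )
    )
    if (!is.na(obs$alt[i])) {
      expect_equal(obs$alt_count[i], unname(sum(sapply(oracle$by_hap, `[[`, obs$alt[i]))))
    }
  }
})

test_that("error-free mosaic alt reads all phase to the mosaic haplotype", {
  fx <- small_sim(noisy = FALSE)
  g <- fx$genome
  frag <- build_fragments(fx$sim$reads, g$truth$hets, mode = "full")
  obs <- site_phase_summary(frag$reads, g$truth$mosaic$pos, g$reference,
    fragments = frag$fragments, candidate_allele = g$truth$mosaic$alt
  )
  for (i in seq_len(nrow(obs))) {
    hap <- g$truth$mosaic$haplotype[i]
    on_mosaic <- if (hap == "H1") obs$alt_h1[i] else obs$alt_h2[i]
    off_mosaic <- if (hap == "H1") obs$alt_h2[i] else obs$alt_h1[i]
    expect_equal(off_mosaic, 0L)
    expect_equal(obs$discordant_count[i], on_mosaic)
  }
})
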