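## shared fixture: trained model + calls on the noisy simulation
fx_call <- small_sim(noisy = TRUE, seed = 13)
.call_env <- local({
  g <- fx_call$genome
  frag <- build_fragments(fx_call$sim$reads, g$truth$hets, mode = "full")
  sel <- select_training_sites(fx_call$sim$reads, g$reference, frag,
    fx_call$germ,
    n_pos = 60, n_neg = 60, seed = 77, exclude = g$truth$mosaic
  )
  ts <- build_training_set(fx_call$sim$reads, g$reference, frag, sel, mode = "full")
  model <- train_model(ts, seed = 3)
  calls <- call_variants(
    fx_call$sim$reads, g$reference, g$truth$hets, fx_call$germ, model,
    fragments = frag
  )
  list(g = g, frag = frag, model = model, calls = calls, ts = ts)
})

test_that("scoring is pure and refuses mismatched feature sets", {
  e <- .call_env
  f <- extract_features(
    site_phase_summary(e$frag$reads, e$g$truth$mosaic$pos, e$g$reference,
      fragments = e$frag$fragments, candidate_allele = e$g$truth$mosaic$alt
    ),
    "full"
  )
  s1 <- score_sites(e$model, f)
  s2 <- score_sites(e$model, f)
  expect_identical(s1, s2)
  expect_true(all(s1 >= 0 & s1 <= 1))
  ## permuted feature columns -> fatal
  expect_error(score_sites(e$model, rev(f)), "feature names")
  expect_error(score_sites(e$model, f[, -1]), "feature names")
})

test_that("region filters label overlapping calls without deleting any", {
  calls <- tibble::tibble(
    chrom = "chr1", pos = c(100L, 500L),
    filters_failed = list(character(0), character(0)),
    pass = c(TRUE, TRUE)
  )
  mask <- region_mask(tibble::tibble(chrom = "chr1", start = 50L, end = 150L), "repeat")
  out <- apply_region_filters(calls, list(mask))
  expect_equal(nrow(out), 2)
  expect_true("region_repeat" %in% out$filters_failed[[1]])
  expect_length(out$filters_failed[[2]], 0)
  expect_equal(out$pass, c(FALSE, TRUE))
  ## empty mask list leaves calls unchanged
  expect_equal(apply_region_filters(calls, list()), calls)
})

test_that("region labels match brute-force interval membership on fuzzed data", {
  set.seed(55)
  calls <- tibble::tibble(
    chrom = sample(c("c1", "c2"), 100, TRUE),
    pos = sample.int(10000, 100),
    filters_failed = rep(list(character(0)), 100),
    pass = TRUE
  )
  starts <- sample.int(9000, 30)
  masks <- list(
    region_mask(tibble::tibble(
      chrom = sample(c("c1", "c2"), 30, TRUE),
      start = starts, end = starts + sample.int(500, 30)
    ), "repeat"),
    region_mask(tibble::tibble(
      chrom = "c1", start = c(0L, 5000L), end = c(1000L, 9000L)
    ), "cnv")
  )
  out <- apply_region_filters(calls, masks)
  for (i in seq_len(nrow(calls))) {
    expect_equal(
      "region_repeat" %in% out$filters_failed[[i]],
      oracle_in_mask(masks[[1]], calls$chrom[i], calls$pos[i])
    )
    expect_equal(
      "region_cnv" %in% out$filters_failed[[i]],
      oracle_in_mask(masks[[2]], calls$chrom[i], calls$pos[i])
    )
  }
})

test_that("alignment-error heuristic follows its four rules", {
  cfg <- call_config()
  ref <- paste0(strrep("ACGT", 50), strrep("G", 12), strrep("ACGT", 50))
  mk_detail <- function(n, clip = 0L, n_mm = 1L, proper = TRUE) {
    tibble::tibble(
      base = rep("T", n), clip_len = clip, n_mm = n_mm,
      is_proper_pair = proper
    )
  }
  ## clean candidate reads pass
  expect_true(alignment_error_filter(mk_detail(4), "T", 10, ref, cfg)$pass)
  ## all reads heavily clipped -> fail (a)
  expect_false(alignment_error_filter(mk_detail(4, clip = 20L), "T", 10, ref, cfg)$pass)
  ## high mismatch load -> fail (b)
  expect_false(alignment_error_filter(mk_detail(4, n_mm = 6L), "T", 10, ref, cfg)$pass)
  ## improper pairs -> fail (c)
  expect_false(alignment_error_filter(mk_detail(4, proper = FALSE), "T", 10, ref, cfg)$pass)
  ## homopolymer run >= 10 bp -> fail (d), regardless of read cleanliness
  expect_false(alignment_error_filter(mk_detail(4), "T", 205, ref, cfg)$pass)
})

test_that("alignment-error decisions match an independent predicate on fuzzed reads", {
  set.seed(66)
  ref <- paste(sample(c("A", "C", "G", "T"), 2000, TRUE), collapse = "")
  cfg <- call_config()
  homop_pos <- mosaiclr:::in_homopolymer(ref, 0:1999, cfg$homopolymer_len)
  for (rep in 1:200) {
    n <- sample(0:8, 1)
    clip <- sample(c(0L, 3L, 6L, 20L), n, TRUE)
    n_mm <- sample(0:6, n, TRUE)
    proper <- sample(c(TRUE, FALSE), n, TRUE, prob = c(0.8, 0.2))
    pos <- sample(0:1999, 1)
    detail <- tibble::tibble(
      base = rep("T", n), clip_len = clip, n_mm = n_mm, is_proper_pair = proper
    )
    got <- alignment_error_filter(detail, "T", pos, ref, cfg)$pass
    want <- oracle_alignment_filter(clip, n_mm, proper, homop_pos[pos + 1], cfg)
    expect_equal(got, want)
  }
})

test_that("end-to-end calls respect the discordant floor and provenance", {
  e <- .call_env
  calls <- e$calls
  truth <- e$g$truth$mosaic
  ## every candidate appears once: PASS or with non-empty failed filters
  expect_true(all(calls$pass == (vapply(calls$filters_failed, length, integer(1)) == 0L)))
  ## a site with 3 discordant reads carries the min_discordant label
  under <- calls[calls$discordant_count < 4, ]
  expect_true(all(vapply(
    under$filters_failed, function(f) "min_discordant" %in% f, logical(1)
  )))
  ## PASS calls are truth-concordant here (no systematic artifacts simulated)
  pass <- calls[calls$pass, ]
  expect_true(all(paste(pass$pos, pass$alt) %in% paste(truth$pos, truth$alt)))
  ## and cover at least half of well-supported truth
  sup <- fx_call$sim$mosaic_support
  well <- sup[sup$alt_support >= 4, ]
  expect_gte(mean(well$pos %in% pass$pos), 0.5)
  ## relaxing the floor from 4 to 3 only adds PASS calls
  relaxed <- call_variants(
    fx_call$sim$reads, e$g$reference, e$g$truth$hets, fx_call$germ, e$model,
    call_cfg = call_config(min_discordant = 3L), fragments = e$frag
  )
  expect_true(all(calls$pos[calls$pass] %in% relaxed$pos[relaxed$pass]))
  expect_gte(sum(relaxed$pass), sum(calls$pass))
})

test_that("score threshold sweep yields a monotone recall trade-off", {
  e <- .call_env
  sup <- fx_call$sim$mosaic_support
  recalls <- vapply(c(0.1, 0.3, 0.5, 0.7, 0.9), function(th) {
    calls <- call_variants(
      fx_call$sim$reads, e$g$reference, e$g$truth$hets, fx_call$germ, e$model,
      call_cfg = call_config(score_threshold = th), fragments = e$frag
    )
    precision_recall(calls, sup, min_support = 4)$overall$recall
  }, numeric(1))
  expect_true(all(diff(recalls) <= 1e-9))
})

test_that("model/fragment mode mismatch is fatal before scoring", {
  e <- .call_env
  frag_np <- build_fragments(fx_call$sim$reads, e$g$truth$hets, mode = "no_phasing")
  expect_error(
    call_variants(
      fx_call$sim$reads, e$g$reference, e$g$truth$hets, fx_call$germ,
      e$model,
      fragments = frag_np
    ),
    "mode"
  )
})
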