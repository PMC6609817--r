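fx_train <- small_sim(noisy = TRUE, seed = 13)

test_that("training-site selection is deterministic and respects exclusions", {
  g <- fx_train$genome
  frag <- build_fragments(fx_train$sim$reads, g$truth$hets, mode = "full")
  sel1 <- select_training_sites(fx_train$sim$reads, g$reference, frag,
    fx_train$germ,
    n_pos = 50, n_neg = 50, seed = 99,
    exclude = g$truth$mosaic
  )
  sel2 <- select_training_sites(fx_train$sim$reads, g$reference, frag,
    fx_train$germ,
    n_pos = 50, n_neg = 50, seed = 99,
    exclude = g$truth$mosaic
  )
  expect_equal(sel1$specs, sel2$specs)
  expect_equal(sel1$negatives, sel2$negatives)
  ## spike positions stay clear of evaluation truth and of germline variants
  for (p in sel1$specs$pos) {
    expect_true(all(abs(g$truth$mosaic$pos - p) >= 1000))
  }
  expect_false(any(sel1$specs$pos %in% fx_train$germ$pos))
  ## negatives split evenly by class
  expect_equal(sum(sel1$negatives$genotype_class == "het"), 25)
  expect_equal(sum(sel1$negatives$genotype_class == "hom_alt"), 25)
  ## pairwise spacing keeps edits independent
  d <- diff(sort(sel1$specs$pos))
  expect_true(all(d >= 500))
  ## an impossible request fails loudly with counts
  expect_error(
    select_training_sites(fx_train$sim$reads, g$reference, frag,
      fx_train$germ,
      n_pos = 50, n_neg = 1e6, seed = 1
    ),
    "insufficient"
  )
})

test_that("target MAF draws are uniform on [0.05, 0.5]", {
  g <- fx_train$genome
  frag <- build_fragments(fx_train$sim$reads, g$truth$hets, mode = "full")
  sel <- select_training_sites(fx_train$sim$reads, g$reference, frag,
    fx_train$germ,
    n_pos = 100, n_neg = 10, seed = 5, min_spacing = 100
  )
  ## mean of U(0.05, 0.5) is 0.275; MC error with n=100 ~ 0.013
  expect_equal(mean(sel$specs$target_maf), 0.275, tolerance = 0.2)
  expect_true(all(sel$specs$target_maf >= 0.05 & sel$specs$target_maf <= 0.5))
  expect_true(all(sel$specs$mosaic_allele != sel$specs$ref))
})

test_that("spike-in edits only the target haplotype, at the intended rate", {
  g <- fx_train$genome
  frag <- build_fragments(fx_train$sim$reads, g$truth$hets, mode = "full")
  sel <- select_training_sites(fx_train$sim$reads, g$reference, frag,
    fx_train$germ,
    n_pos = 60, n_neg = 10, seed = 31,
    exclude = g$truth$mosaic
  )
  specs <- sel$specs
  specs$target_maf <- 0.2
  achieved <- numeric(nrow(specs))
  for (i in seq_len(nrow(specs))) {
    res <- spike_in(frag$reads, frag$fragments, specs[i, ])
    achieved[i] <- res$achieved_maf
    ## differences vs the original reads must lie on carrier fragments only
    changed <- which(res$reads$seq != frag$reads$seq)
    if (length(changed)) {
      haps <- frag$fragments$haplotype[match(
        res$reads$fragment_id[changed], frag$fragments$fragment_id
      )]
      other <- setdiff(c("H1", "H2"), specs$target_haplotype[i])
      expect_false(any(haps == other))
      ## edits are exactly at the site, to the mosaic allele
      off <- specs$pos[i] - res$reads$start[changed] + 1L
      expect_true(all(substr(res$reads$seq[changed], off, off) == specs$mosaic_allele[i]))
    }
  }
  ## binomial expectation: mean achieved MAF near the 0.2 target
  expect_equal(mean(achieved, na.rm = TRUE), 0.2, tolerance = 0.15)
  expect_true(abs(mean(achieved, na.rm = TRUE) - 0.2) < 0.03)
  ## degenerate target rejected
  bad <- specs[1, ]
  bad$target_maf <- 0
  expect_error(spike_in(frag$reads, frag$fragments, bad))
})

test_that("training sets label rows correctly and separate the classes", {
  g <- fx_train$genome
  frag <- build_fragments(fx_train$sim$reads, g$truth$hets, mode = "full")
  sel <- select_training_sites(fx_train$sim$reads, g$reference, frag,
    fx_train$germ,
    n_pos = 60, n_neg = 60, seed = 77,
    exclude = g$truth$mosaic
  )
  ts <- build_training_set(fx_train$sim$reads, g$reference, frag, sel, mode = "full")
  expect_s3_class(ts, "mosaic_training_set")
  expect_equal(nrow(ts$features), length(ts$labels))
  expect_equal(nrow(ts$provenance), length(ts$labels))
  ## labels align with provenance
  expect_true(all(ts$provenance$origin[ts$labels == "positive"] == "spike_in"))
  expect_true(all(ts$provenance$origin[ts$labels == "negative"] %in% c("het", "hom_alt")))
  expect_true(all(!is.na(ts$provenance$achieved_maf[ts$labels == "positive"])))
  ## the haplotype signature: spiked sites concentrate on one haplotype far
  ## more than het negatives do on theirs at candidate level
  conc_pos <- ts$features$hap_concentration[ts$labels == "positive"]
  het_rows <- ts$labels == "negative" & ts$provenance$origin == "het"
  expect_true(mean(conc_pos) > 0.95)
  expect_true(
    mean(ts$features$maf[ts$labels == "positive"]) <
      mean(ts$features$maf[het_rows])
  )
})

test_that("forest training honors tree count, determinism and class checks", {
  ## linearly separable toy set built directly in feature space
  n <- 60
  toy_feats <- as_tibble_fill <- NULL
  fn <- feature_names("full")
  mk <- function(conc) {
    df <- tibble::as_tibble(setNames(
      lapply(fn, function(x) runif(n)), fn
    ))
    df$hap_concentration <- conc
    df
  }
  set.seed(4)
  ts <- structure(
    list(
      features = dplyr::bind_rows(mk(1.0), mk(0.5)),
      labels = factor(rep(c("positive", "negative"), each = n),
        levels = c("negative", "positive")
      ),
      provenance = tibble::tibble(origin = rep(c("spike_in", "het"), each = n)),
      mode = "full"
    ),
    class = "mosaic_training_set"
  )
  model <- train_model(ts, seed = 8)
  expect_equal(model$n_trees, 100L)
  expect_equal(model$forest$num.trees, 100)
  expect_identical(model$feature_names, fn)
  ## perfect training accuracy on the separable set
  sc <- score_sites(model, ts$features)
  expect_true(all(sc[ts$labels == "positive"] > 0.5))
  expect_true(all(sc[ts$labels == "negative"] < 0.5))
  ## duplicate of a training positive scores high
  expect_true(score_sites(model, ts$features[1, ]) > 0.5)
  ## same seed -> byte-identical serialized artifact
  m2 <- train_model(ts, seed = 8)
  p1 <- tempfile()
  p2 <- tempfile()
  write_model(model, p1)
  write_model(m2, p2)
  expect_identical(
    digest::digest(p1, file = TRUE),
    digest::digest(p2, file = TRUE)
  )
  ## reloaded artifact scores identically
  m3 <- read_model(p1)
  expect_identical(score_sites(m3, ts$features), sc)
  ## single-class input is fatal
  ts_bad <- ts
  ts_bad$labels <- factor(rep("positive", 2 * n), levels = c("negative", "positive"))
  expect_error(train_model(ts_bad), "single class|single-class|both")
  ## glance/tidy accessors
  expect_equal(glance(model)$n_trees, 100L)
  expect_true(all(tidy(model)$feature %in% fn))
})

test_that("held-out mosaic sites outscore held-out germline hets", {
  g <- fx_train$genome
  frag <- build_fragments(fx_train$sim$reads, g$truth$hets, mode = "full")
  sel <- select_training_sites(fx_train$sim$reads, g$reference, frag,
    fx_train$germ,
    n_pos = 60, n_neg = 60, seed = 77,
    exclude = g$truth$mosaic
  )
  ts <- build_training_set(fx_train$sim$reads, g$reference, frag, sel, mode = "full")
  model <- train_model(ts, seed = 3)
  ## held out: the simulated mosaic truth vs unused het sites
  mos_obs <- site_phase_summary(frag$reads, g$truth$mosaic$pos, g$reference,
    fragments = frag$fragments, candidate_allele = g$truth$mosaic$alt
  )
  unused_hets <- dplyr::anti_join(
    g$truth$hets,
    dplyr::filter(sel$negatives, .data$genotype_class == "het"),
    by = "pos"
  )
  het_obs <- site_phase_summary(frag$reads, unused_hets$pos, g$reference,
    fragments = frag$fragments, candidate_allele = unused_hets$alt
  )
  s_mos <- score_sites(model, extract_features(mos_obs, "full"))
  s_het <- score_sites(model, extract_features(het_obs, "full"))
  wt <- stats::wilcox.test(s_mos, s_het, alternative = "greater", exact = FALSE)
  expect_lt(wt$p.value, 1e-4)
})
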