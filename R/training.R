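#' Select spike-in (positive) and germline (negative) training sites
#'
#' Spike-in positions are homozygous-reference, pass the scan depth and
#' phased-fraction requirements before editing, lie at least `min_dist` bp
#' from any supplied exclusion site (e.g. evaluation truth — training and
#' evaluation sets must be disjoint), and are mutually separated by at least
#' `min_spacing` bp so edits never interact. Each gets a target allele
#' fraction drawn uniformly from [0.05, 0.5], a target haplotype drawn
#' uniformly, and a mosaic allele drawn uniformly from the three
#' non-reference bases. Negatives are sampled evenly from het and
#' homozygous-alt germline sites.
#'
#' @param reads Read tibble (one chromosome).
#' @param reference Reference sequence.
#' @param fragments [build_fragments()] result for `reads` (full mode).
#' @param germline Germline tibble (`chrom`, `pos`, `ref`, `alt`,
#'   `genotype_class`).
#' @param n_pos,n_neg Numbers of positive and negative examples.
#' @param seed Integer seed.
#' @param cfg A [scan_config()] (depth/phasing eligibility).
#' @param exclude Optional tibble of `pos` values to stay `min_dist` away
#'   from (evaluation truth sites).
#' @param min_dist Exclusion radius around `exclude` sites (default 1000).
#' @param min_spacing Minimum distance between chosen spike-ins (default 500).
#' @return List with `specs` (tibble `chrom`, `pos`, `ref`, `target_maf`,
#'   `target_haplotype`, `mosaic_allele`, `seed`) and `negatives` (tibble of
#'   germline sites with `genotype_class`).
#' @export
select_training_sites <- function(reads, reference, fragments, germline,
                                  n_pos = 200L, n_neg = n_pos,
                                  seed = 1L, cfg = scan_config(),
                                  exclude = NULL, min_dist = 1000L,
                                  min_spacing = 500L) {
  set.seed(stage_seed(seed, "select_training_sites"))
  ref <- as_ref_string(reference)
  L <- nchar(ref)
  chrom <- reads$chrom[1]
  germ_pos <- germline$pos[germline$genotype_class %in% c("het", "hom_alt")]
  ## candidate pool: random positions away from variants and exclusions
  pool <- sample.int(L, min(L, n_pos * 30L)) - 1L
  pool <- setdiff(pool, germ_pos)
  if (!is.null(exclude) && nrow(exclude)) {
    near <- vapply(
      pool, function(p) any(abs(exclude$pos - p) < min_dist), logical(1)
    )
    pool <- pool[!near]
  }
  if (length(pool) == 0) {
    abort("no eligible spike-in positions remain after exclusions")
  }
  ## greedy spacing, deterministic in pool order
  chosen <- integer(0)
  for (p in pool) {
    if (length(chosen) >= n_pos * 3L) break
    if (!length(chosen) || all(abs(chosen - p) >= min_spacing)) {
      chosen <- c(chosen, p)
    }
  }
  ## pre-edit eligibility: depth and phasing, measured like the scanner
  obs <- site_phase_summary(
    fragments$reads, chosen, ref,
    fragments = fragments$fragments,
    candidate_allele = "N", mode = fragments$mode %||% "full",
    min_mapq = cfg$min_mapq, min_bq = cfg$min_bq
  )
  ok <- obs$depth >= cfg$min_depth & obs$phased_fraction >= cfg$min_phased_fraction
  eligible <- chosen[ok]
  if (length(eligible) < n_pos) {
    abort(sprintf(
      "insufficient eligible spike-in sites: needed %d, found %d (of %d probed)",
      n_pos, length(eligible), length(chosen)
    ))
  }
  pos <- sort(eligible[seq_len(n_pos)])
  refbase <- substring(ref, pos + 1L, pos + 1L)
  specs <- tibble(
    chrom = chrom,
    pos = pos,
    ref = refbase,
    target_maf = runif(n_pos, 0.05, 0.5),
    target_haplotype = sample(c("H1", "H2"), n_pos, replace = TRUE),
    mosaic_allele = random_other_base(refbase),
    seed = stage_seed(seed, "spike") + seq_len(n_pos)
  )
  hets <- dplyr::filter(germline, .data$genotype_class == "het")
  homs <- dplyr::filter(germline, .data$genotype_class == "hom_alt")
  n_het <- ceiling(n_neg / 2)
  n_hom <- n_neg - n_het
  if (nrow(hets) < n_het || nrow(homs) < n_hom) {
    abort(sprintf(
      "insufficient germline negatives: need %d het (have %d) and %d hom_alt (have %d)",
      n_het, nrow(hets), n_hom, nrow(homs)
    ))
  }
  negatives <- bind_rows(
    dplyr::slice(hets, sort(sample.int(nrow(hets), n_het))),
    dplyr::slice(homs, sort(sample.int(nrow(homs), n_hom)))
  )
  list(specs = specs, negatives = negatives)
}

## fragment-granular selection for one spike: returns logical over fragments
select_spike_fragments <- function(fragments, spec) {
  set.seed(spec$seed)
  on_target <- fragments$haplotype == spec$target_haplotype
  unassigned <- fragments$haplotype == "unassigned"
  covers <- fragments$start <= spec$pos & fragments$end > spec$pos
  u <- runif(nrow(fragments))
  covers & (
    (on_target & u < pmin(1, 2 * spec$target_maf)) |
      (unassigned & u < spec$target_maf)
  )
}

#' Spike a synthetic mosaic allele into aligned reads at one site
#'
#' Editing is fragment-granular: each fragment assigned to the target
#' haplotype is selected with probability `min(1, 2 * target_maf)`, each
#' unassigned fragment with probability `target_maf`, and fragments on the
#' other haplotype are never edited. Every read of a selected fragment with
#' an aligned base at the position has that base replaced by the mosaic
#' allele (base quality unchanged). The achieved allele fraction
#' (edited reads / counted depth) is returned and recorded.
#'
#' @param reads Read tibble with `fragment_id`.
#' @param fragments Haplotype-assigned fragment tibble.
#' @param spec One-row tibble/list: `pos`, `target_maf`, `target_haplotype`,
#'   `mosaic_allele`, `seed` (see [select_training_sites()]).
#' @param cfg [scan_config()] supplying the counting floors for the
#'   achieved-MAF denominator.
#' @return List: `reads` (edited tibble), `achieved_maf`, `n_edited`.
#' @export
spike_in <- function(reads, fragments, spec, cfg = scan_config()) {
  stopifnot(spec$target_maf > 0, spec$target_maf <= 0.5)
  sel <- select_spike_fragments(fragments, spec)
  rows <- which(reads$fragment_id %in% fragments$fragment_id[sel] &
    reads$start <= spec$pos & reads$end > spec$pos)
  n_edited <- 0L
  if (length(rows)) {
    off <- query_offset(reads$cigar[rows], reads$start[rows], rep(spec$pos, length(rows)))
    rows <- rows[!is.na(off)]
    off <- off[!is.na(off)]
    for (k in seq_along(rows)) {
      substr(reads$seq[rows[k]], off[k] + 1L, off[k] + 1L) <- spec$mosaic_allele
    }
    n_edited <- length(rows)
  }
  cm <- counted_mask(reads, cfg$min_mapq)
  covers <- cm & reads$start <= spec$pos & reads$end > spec$pos
  depth <- sum(covers)
  if (depth == 0) {
    warn(sprintf("spike-in at pos %d skipped: zero depth", spec$pos))
    return(list(reads = reads, achieved_maf = NA_real_, n_edited = 0L))
  }
  list(reads = reads, achieved_maf = n_edited / depth, n_edited = n_edited)
}

#' Build a labelled training set from spike-ins and germline negatives
#'
#' Positive examples are the spiked sites, featurised on the edited pileups
#' with the mosaic allele as candidate; negatives are germline het and
#' hom-alt sites featurised on the unedited pileups with the germline alt as
#' candidate. Positives whose post-edit pileup fails the scan filter are
#' dropped and logged.
#'
#' @param reads Read tibble (unedited).
#' @param reference Reference sequence.
#' @param fragments [build_fragments()] result matching `mode` (drives
#'   feature extraction).
#' @param selection Result of [select_training_sites()].
#' @param mode Model variant.
#' @param cfg A [scan_config()].
#' @param edit_fragments [build_fragments()] result in `full` mode used for
#'   the haplotype-aware editing itself; spiking is physical-molecule
#'   granular regardless of the feature mode. Defaults to `fragments`.
#' @return A `mosaic_training_set`: list with `features` (tibble),
#'   `labels` (factor `positive`/`negative`), `provenance` (tibble with
#'   `chrom`, `pos`, `origin`, `achieved_maf`), `mode`.
#' @export
build_training_set <- function(reads, reference, fragments, selection,
                               mode = c("full", "short_only", "no_phasing"),
                               cfg = scan_config(), edit_fragments = NULL) {
  mode <- match.arg(mode)
  ref <- as_ref_string(reference)
  specs <- selection$specs
  negatives <- selection$negatives
  if (is.null(edit_fragments)) edit_fragments <- fragments
  ## edit on physical molecules, featurise under the requested mode
  ed <- edit_fragments$reads
  achieved <- numeric(nrow(specs))
  for (i in seq_len(nrow(specs))) {
    res <- spike_in(ed, edit_fragments$fragments, specs[i, ], cfg = cfg)
    ed <- res$reads
    achieved[i] <- res$achieved_maf
  }
  ## carry the edited sequences over to the mode-specific read grouping
  rd <- fragments$reads
  rd$seq <- ed$seq[match(
    paste(rd$read_name, rd$start, rd$is_read1),
    paste(ed$read_name, ed$start, ed$is_read1)
  )]
  frg <- fragments$fragments
  pos_obs <- site_phase_summary(
    rd, specs$pos, ref,
    fragments = frg,
    candidate_allele = specs$mosaic_allele,
    mode = mode, min_mapq = cfg$min_mapq, min_bq = cfg$min_bq
  )
  keep_pos <- passes_site_filter(pos_obs, germline = NULL, cfg, mode = mode)
  n_dropped <- sum(!keep_pos)
  if (n_dropped > 0) {
    inform(sprintf("dropped %d spike-in(s) failing the post-edit scan filter", n_dropped))
  }
  neg_obs <- site_phase_summary(
    fragments$reads, negatives$pos, ref,
    fragments = frg,
    candidate_allele = negatives$alt,
    mode = mode, min_mapq = cfg$min_mapq, min_bq = cfg$min_bq
  )
  keep_neg <- neg_obs$depth > 0
  pos_obs2 <- pos_obs[keep_pos, ]
  attr(pos_obs2, "mode") <- mode
  neg_obs2 <- neg_obs[keep_neg, ]
  attr(neg_obs2, "mode") <- mode
  feats <- bind_rows(
    extract_features(pos_obs2, mode),
    extract_features(neg_obs2, mode)
  )
  labels <- factor(
    c(
      rep("positive", sum(keep_pos)),
      rep("negative", sum(keep_neg))
    ),
    levels = c("negative", "positive")
  )
  provenance <- bind_rows(
    tibble(
      chrom = specs$chrom[keep_pos], pos = specs$pos[keep_pos],
      origin = "spike_in", achieved_maf = achieved[keep_pos]
    ),
    tibble(
      chrom = negatives$chrom[keep_neg], pos = negatives$pos[keep_neg],
      origin = negatives$genotype_class[keep_neg], achieved_maf = NA_real_
    )
  )
  structure(
    list(
      features = feats, labels = labels, provenance = provenance,
      mode = mode, n_dropped_positives = n_dropped
    ),
    class = "mosaic_training_set"
  )
}

#' Train the random-forest site-scoring model
#'
#' Fits a probability forest of `n_trees` decision trees (default 100) that
#' scores sites by their resemblance to the synthetic mosaic spike-ins. The
#' score is the averaged per-tree probability of the positive class, in
#' `[0, 1]`. Hyperparameters beyond tree count are common defaults
#' (unlimited depth, sqrt-features per split) and are recorded in the
#' artifact together with the feature list, mode and seed, so scoring can
#' refuse mismatched inputs.
#'
#' @param ts A `mosaic_training_set` from [build_training_set()].
#' @param n_trees Ensemble size (default 100).
#' @param seed Integer seed.
#' @return A `mosaic_model` object.
#' @export
train_model <- function(ts, n_trees = 100L, seed = 1L) {
  stopifnot(inherits(ts, "mosaic_training_set"))
  if (dplyr::n_distinct(ts$labels) < 2) {
    abort("training set has a single class; need both positives and negatives")
  }
  df <- as.data.frame(ts$features)
  df$.label <- ts$labels
  forest <- ranger::ranger(
    dependent.variable.name = ".label",
    data = df,
    num.trees = n_trees,
    probability = TRUE,
    importance = "impurity",
    seed = stage_seed(seed, "train_model"),
    num.threads = 1
  )
  forest$call <- NULL
  structure(
    list(
      forest = forest,
      n_trees = as.integer(n_trees),
      mode = ts$mode,
      feature_names = names(ts$features),
      seed = as.integer(seed),
      n_train = nrow(df),
      version = "mosaiclr-model-1"
    ),
    class = "mosaic_model"
  )
}

#' @export
print.mosaic_model <- function(x, ...) {
  cat(sprintf(
    "<mosaic_model> %s mode, %d trees, %d features, trained on %d examples (seed %d)\n",
    x$mode, x$n_trees, length(x$feature_names), x$n_train, x$seed
  ))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
tidy.mosaic_model <- function(x, ...) {
  imp <- x$forest$variable.importance
  tibble(
    feature = names(imp),
    importance = as.numeric(imp)
  ) |> dplyr::arrange(dplyr::desc(.data$importance))
}

#' @importFrom generics glance
#' @export
glance.mosaic_model <- function(x, ...) {
  tibble(
    mode = x$mode,
    n_trees = x$n_trees,
    n_features = length(x$feature_names),
    n_train = x$n_train,
    oob_error = x$forest$prediction.error,
    seed = x$seed,
    version = x$version
  )
}

#' Serialize / restore a model artifact
#'
#' The artifact is self-describing (mode, feature names, seed, version) and
#' reloads with identical scores.
#'
#' @param model A `mosaic_model`.
#' @param path File path.
#' @return `path` (write) or the model (read).
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "mosaic_model"))
  saveRDS(model, path, version = 3, compress = FALSE)
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "mosaic_model")) abort("not a mosaic_model artifact")
  model
}
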