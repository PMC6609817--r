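#' Run the full pipeline on standard files
#'
#' File-level orchestration of the six steps: read inputs, reconstruct and
#' phase molecules, select training sites, spike in synthetic mosaic
#' variants, train the sample-specific forest, scan and score candidates,
#' filter, and write a calls VCF plus a JSON run report and the model
#' artifact. A single global seed is split into per-stage seeds by stable
#' hashing of stage names ([stage_seed()]), so identical seeds give
#' byte-identical outputs and any stage can be reproduced independently.
#'
#' @param bam Indexed BAM of barcoded alignments.
#' @param fasta Reference FASTA.
#' @param vcf Phased germline VCF.
#' @param out_dir Output directory.
#' @param mode Model variant.
#' @param seed Global integer seed.
#' @param n_train Spike-in positives (and germline negatives) for training.
#' @param n_trees Forest size.
#' @param scan_cfg,call_cfg Configurations.
#' @param repeat_bed,cnv_bed Optional exclusion BEDs.
#' @param exclude_training Optional tibble of `pos` to keep training
#'   spike-ins away from (e.g. evaluation truth).
#' @param sample_name VCF sample name.
#' @return List: `calls` tibble, `model`, `paths` (vcf/model/report),
#'   `report` (per-stage counts).
#' @export
run_pipeline <- function(bam, fasta, vcf, out_dir, mode = "full", seed = 1L,
                         n_train = 200L, n_trees = 100L,
                         scan_cfg = scan_config(), call_cfg = call_config(),
                         repeat_bed = NULL, cnv_bed = NULL,
                         exclude_training = NULL, sample_name = "SAMPLE") {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  ref_seqs <- Biostrings::readDNAStringSet(fasta)
  names(ref_seqs) <- sub(" .*", "", names(ref_seqs))
  vc <- read_phased_vcf(vcf)
  masks <- list()
  if (!is.null(repeat_bed)) masks <- c(masks, list(read_bed(repeat_bed, "repeat")))
  if (!is.null(cnv_bed)) masks <- c(masks, list(read_bed(cnv_bed, "cnv")))
  all_calls <- list()
  model <- NULL
  report <- list()
  for (chrom in names(ref_seqs)) {
    reads <- read_alignments(bam, genome_region(chrom, 0, length(ref_seqs[[chrom]])))
    if (nrow(reads) == 0) next
    ref <- as.character(ref_seqs[[chrom]])
    hets <- dplyr::filter(vc$hets, .data$chrom == !!chrom)
    germ <- dplyr::filter(vc$germline, .data$chrom == !!chrom)
    frag_full <- build_fragments(reads, hets,
      mode = "full",
      max_gap = scan_cfg$max_gap, min_bq = scan_cfg$min_bq
    )
    frag_mode <- if (mode == "full") {
      frag_full
    } else {
      build_fragments(reads, hets,
        mode = mode,
        max_gap = scan_cfg$max_gap, min_bq = scan_cfg$min_bq
      )
    }
    if (is.null(model)) {
      sel <- select_training_sites(
        reads, ref, frag_full, germ,
        n_pos = n_train, n_neg = n_train,
        seed = stage_seed(seed, paste0("train:", chrom)),
        cfg = scan_cfg, exclude = exclude_training
      )
      ts <- build_training_set(reads, ref, frag_mode, sel,
        mode = mode,
        cfg = scan_cfg, edit_fragments = frag_full
      )
      model <- train_model(ts, n_trees = n_trees, seed = stage_seed(seed, "forest"))
    }
    calls <- call_variants(
      reads, ref, hets, germ, model,
      masks = masks, scan_cfg = scan_cfg, call_cfg = call_cfg,
      fragments = frag_mode
    )
    report[[chrom]] <- as.list(attr(calls, "report"))
    all_calls[[chrom]] <- calls
  }
  calls <- bind_rows(all_calls)
  if (nrow(calls)) calls <- dplyr::arrange(calls, .data$chrom, .data$pos)
  paths <- list(
    vcf = file.path(out_dir, "mosaic_calls.vcf"),
    model = file.path(out_dir, "model.rds"),
    report = file.path(out_dir, "report.json")
  )
  write_calls_vcf(calls, paths$vcf, sample_name = sample_name)
  if (!is.null(model)) write_model(model, paths$model)
  jsonlite::write_json(
    list(seed = seed, mode = mode, stages = report),
    paths$report,
    auto_unbox = TRUE, pretty = TRUE
  )
  list(calls = calls, model = model, paths = paths, report = report)
}
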