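#' Read phased germline variants from a VCF
#'
#' Parses a phased germline VCF (as produced by a linked-read pipeline such
#' as Long Ranger) into two tibbles: every biallelic SNV as a germline site,
#' and phased heterozygous SNVs additionally as phased hets with per-haplotype
#' alleles taken from the genotype allele order and the phase-set (`PS`)
#' annotation. Multi-allelic and indel records are skipped and counted;
#' records without a genotype are skipped with a warning. Positions are
#' converted from 1-based VCF to 0-based internal coordinates.
#'
#' @param path Path to a VCF (plain or bgzipped).
#' @param region Optional region (see [genome_region()]); records outside
#'   are dropped.
#' @return A list with elements:
#'   * `hets`: tibble `chrom`, `pos`, `ref`, `alt`, `h1`, `h2`, `phase_set`;
#'   * `germline`: tibble `chrom`, `pos`, `ref`, `alt`, `genotype_class`
#'     (`hom_ref`/`het`/`hom_alt`), `phased`;
#'   * `n_skipped`: named counts of skipped records
#'     (`indel`, `multiallelic`, `no_genotype`).
#' @export
read_phased_vcf <- function(path, region = NULL) {
  if (!file.exists(path)) abort(sprintf("VCF not found: %s", path))
  vcf <- suppressWarnings(VariantAnnotation::readVcf(path, genome = "unknown"))
  rr <- SummarizedExperiment::rowRanges(vcf)
  ref <- as.character(VariantAnnotation::ref(vcf))
  alt_list <- VariantAnnotation::alt(vcf)
  n_alt <- S4Vectors::elementNROWS(alt_list)
  alt1 <- rep(NA_character_, length(ref))
  alt1[n_alt >= 1] <- vapply(
    as.list(alt_list[n_alt >= 1]),
    function(a) as.character(a)[1], character(1)
  )
  gt <- VariantAnnotation::geno(vcf)$GT
  if (is.null(gt)) {
    gt <- matrix(NA_character_, nrow = length(ref), ncol = 1)
  }
  gt1 <- as.character(gt[, 1])
  ps <- VariantAnnotation::geno(vcf)$PS
  ps1 <- if (is.null(ps)) rep(NA_character_, length(ref)) else as.character(ps[, 1])

  chrom <- as.character(GenomicRanges::seqnames(rr))
  pos0 <- GenomicRanges::start(rr) - 1L

  multi <- n_alt > 1
  indel <- !multi & (nchar(ref) != 1L | is.na(alt1) | nchar(alt1) != 1L |
    !(ref %in% DNA_BASES) | !(alt1 %in% DNA_BASES))
  no_gt <- !multi & !indel & (is.na(gt1) | gt1 %in% c(".", "./.", ".|."))
  if (any(no_gt)) {
    warn(sprintf("skipping %d VCF record(s) without a genotype", sum(no_gt)))
  }
  keep <- !multi & !indel & !no_gt

  sep_phased <- grepl("|", gt1, fixed = TRUE)
  a <- sub("[/|].*", "", gt1)
  b <- sub(".*[/|]", "", gt1)
  a_i <- suppressWarnings(as.integer(a))
  b_i <- suppressWarnings(as.integer(b))
  valid_gt <- keep & !is.na(a_i) & !is.na(b_i) & a_i <= 1 & b_i <= 1
  keep <- valid_gt

  gclass <- dplyr::case_when(
    a_i + b_i == 0L ~ "hom_ref",
    a_i + b_i == 2L ~ "hom_alt",
    TRUE ~ "het"
  )
  germline <- tibble(
    chrom = chrom[keep], pos = pos0[keep], ref = ref[keep], alt = alt1[keep],
    genotype_class = gclass[keep],
    phased = sep_phased[keep]
  )
  is_phet <- keep & gclass == "het" & sep_phased
  allele_of <- function(i, idx) ifelse(idx == 0L, ref[i], alt1[i])
  hets <- tibble(
    chrom = chrom[is_phet], pos = pos0[is_phet],
    ref = ref[is_phet], alt = alt1[is_phet],
    h1 = allele_of(which(is_phet), a_i[is_phet]),
    h2 = allele_of(which(is_phet), b_i[is_phet]),
    phase_set = ifelse(is.na(ps1[is_phet]), "0", ps1[is_phet])
  )
  if (!is.null(region)) {
    region <- as_region(region)
    germline <- dplyr::filter(
      germline, .data$chrom == region$chrom,
      .data$pos >= region$start, .data$pos < region$end
    )
    hets <- dplyr::filter(
      hets, .data$chrom == region$chrom,
      .data$pos >= region$start, .data$pos < region$end
    )
  }
  list(
    hets = dplyr::arrange(hets, .data$chrom, .data$pos),
    germline = dplyr::arrange(germline, .data$chrom, .data$pos),
    n_skipped = c(
      indel = sum(indel), multiallelic = sum(multi),
      no_genotype = sum(no_gt)
    )
  )
}

#' Write germline truth (phased hets and homozygous sites) as VCF
#'
#' Used by the simulator to emit its germline truth in the format the
#' pipeline consumes; round-trips through [read_phased_vcf()].
#'
#' @param hets Tibble with `chrom`, `pos`, `ref`, `alt`, `h1`, `h2`,
#'   `phase_set`.
#' @param homs Optional tibble with `chrom`, `pos`, `ref`, `alt` of
#'   homozygous-alt sites.
#' @param path Output path.
#' @param sample_name Sample column name.
#' @return `path`, invisibly.
#' @export
write_phased_vcf <- function(hets, path, homs = NULL, sample_name = "SAMPLE") {
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##source=mosaiclr-simulator",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=PS,Number=1,Type=String,Description=\"Phase set\">",
    paste0(
      "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\t",
      sample_name
    )
  )
  recs <- tibble(
    chrom = character(), pos = integer(), ref = character(),
    alt = character(), gt = character(), ps = character()
  )
  if (nrow(hets)) {
    gt <- ifelse(hets$h1 == hets$ref, "0|1", "1|0")
    recs <- bind_rows(recs, tibble(
      chrom = hets$chrom, pos = hets$pos, ref = hets$ref, alt = hets$alt,
      gt = gt, ps = as.character(hets$phase_set)
    ))
  }
  if (!is.null(homs) && nrow(homs)) {
    recs <- bind_rows(recs, tibble(
      chrom = homs$chrom, pos = homs$pos, ref = homs$ref, alt = homs$alt,
      gt = "1/1", ps = NA_character_
    ))
  }
  recs <- dplyr::arrange(recs, .data$chrom, .data$pos)
  lines <- sprintf(
    "%s\t%d\t.\t%s\t%s\t.\tPASS\t.\t%s\t%s",
    recs$chrom, recs$pos + 1L, recs$ref, recs$alt,
    ifelse(is.na(recs$ps), "GT", "GT:PS"),
    ifelse(is.na(recs$ps), recs$gt, paste0(recs$gt, ":", recs$ps))
  )
  writeLines(c(hdr, lines), path)
  invisible(path)
}

#' Write mosaic calls as VCF 4.2
#'
#' Emits one record per scored candidate with INFO fields `SCORE` (forest
#' score), `MAF` (observed mosaic allele fraction), `DISC` (haplotype-
#' discordant read count) and `HAP` (majority haplotype of candidate reads).
#' The FILTER column mirrors the call's failed filters (`PASS` when none).
#' Internal 0-based positions are re-encoded 1-based.
#'
#' @param calls Call tibble from [call_variants()] (columns `chrom`, `pos`,
#'   `ref`, `alt`, `score`, `maf`, `depth`, `discordant_count`, `haplotype`,
#'   `filters_failed` list-column, `pass`). Must be sorted by chrom, pos.
#' @param path Output path.
#' @param sample_name Sample column name.
#' @return `path`, invisibly.
#' @export
write_calls_vcf <- function(calls, path, sample_name = "SAMPLE") {
  if (nrow(calls) > 0) {
    o <- order(calls$chrom, calls$pos)
    if (!identical(o, seq_len(nrow(calls)))) {
      abort("calls must be sorted by chrom, pos before writing")
    }
  }
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##source=mosaiclr",
    "##INFO=<ID=SCORE,Number=1,Type=Float,Description=\"Random-forest mosaic score\">",
    "##INFO=<ID=MAF,Number=1,Type=Float,Description=\"Observed mosaic allele fraction\">",
    "##INFO=<ID=DISC,Number=1,Type=Integer,Description=\"Haplotype-discordant read count\">",
    "##INFO=<ID=HAP,Number=1,Type=String,Description=\"Majority haplotype of candidate reads\">",
    "##FILTER=<ID=region_repeat,Description=\"Overlaps repeat mask\">",
    "##FILTER=<ID=region_cnv,Description=\"Overlaps non-diploid copy-number mask\">",
    "##FILTER=<ID=alignment_error,Description=\"Alignment-error heuristic\">",
    "##FILTER=<ID=min_discordant,Description=\"Too few haplotype-discordant reads\">",
    "##FILTER=<ID=low_score,Description=\"Forest score below threshold\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste0(
      "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\t",
      sample_name
    )
  )
  if (nrow(calls) == 0) {
    writeLines(hdr, path)
    return(invisible(path))
  }
  filt <- vapply(calls$filters_failed, function(f) {
    if (length(f) == 0) "PASS" else paste(sort(f), collapse = ";")
  }, character(1))
  info <- sprintf(
    "SCORE=%.6f;MAF=%.6f;DISC=%d;HAP=%s",
    calls$score, calls$maf, as.integer(calls$discordant_count), calls$haplotype
  )
  lines <- sprintf(
    "%s\t%d\t.\t%s\t%s\t.\t%s\t%s\tGT\t0/1",
    calls$chrom, calls$pos + 1L, calls$ref, calls$alt, filt, info
  )
  writeLines(c(hdr, lines), path)
  invisible(path)
}

#' Read a mosaic-call VCF back into a tibble
#'
#' Inverse of [write_calls_vcf()]; used for round-trips and for evaluating
#' call files produced by earlier pipeline runs.
#'
#' @param path VCF path.
#' @return Call tibble with `chrom`, `pos` (0-based), `ref`, `alt`, `score`,
#'   `maf`, `discordant_count`, `haplotype`, `filters_failed`, `pass`.
#' @export
read_calls_vcf <- function(path) {
  vcf <- suppressWarnings(VariantAnnotation::readVcf(path, genome = "unknown"))
  rr <- SummarizedExperiment::rowRanges(vcf)
  n <- length(rr)
  if (n == 0) {
    return(tibble(
      chrom = character(), pos = integer(), ref = character(),
      alt = character(), score = double(), maf = double(),
      discordant_count = integer(), haplotype = character(),
      filters_failed = list(), pass = logical()
    ))
  }
  info <- VariantAnnotation::info(vcf)
  filt <- as.character(rr$FILTER)
  ff <- lapply(filt, function(f) {
    if (is.na(f) || f %in% c("PASS", ".")) character(0) else strsplit(f, ";")[[1]]
  })
  tibble(
    chrom = as.character(GenomicRanges::seqnames(rr)),
    pos = GenomicRanges::start(rr) - 1L,
    ref = as.character(VariantAnnotation::ref(vcf)),
    alt = vapply(as.list(VariantAnnotation::alt(vcf)), function(a) as.character(a)[1], character(1)),
    score = as.numeric(info$SCORE),
    maf = as.numeric(info$MAF),
    discordant_count = as.integer(info$DISC),
    haplotype = as.character(info$HAP),
    filters_failed = ff,
    pass = vapply(ff, length, integer(1)) == 0L
  )
}
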