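#' Linked-read simulation configuration
#'
#' Describes the synthetic substrate: a diploid genome with phased
#' heterozygotes and homozygous-alt germline variants, long fragments with
#' heavy-tailed (lognormal) lengths sequenced internally at low coverage by
#' barcoded read pairs, i.i.d. base errors, and mosaic variants restricted
#' to one haplotype at controlled minor allele fractions. Fragment-length
#' defaults (mean 16,176 bp, SD 54,387 bp) and ~0.1-fold internal coverage
#' match a typical 10x-style linked-read library.
#'
#' @param region_length Simulated chromosome length (bp).
#' @param het_rate Per-bp probability of a phased heterozygote.
#' @param hom_rate Per-bp probability of a homozygous-alt germline site
#'   (used as training negatives alongside hets).
#' @param n_mosaic Number of mosaic truth sites.
#' @param mosaic_mafs Allele fractions sampled per mosaic site, in (0, 0.5].
#' @param coverage Target genome-wide read coverage (fold).
#' @param read_length Read length (bp).
#' @param insert_mean,insert_sd Paired-end insert size (bp).
#' @param fragment_length_mean,fragment_length_sd Long-fragment length (bp).
#' @param fragment_internal_coverage Fold coverage of each fragment by its
#'   own reads.
#' @param base_error_rate Per-base substitution error probability.
#' @param seed Integer seed.
#' @param chrom Chromosome name.
#' @return A `sim_config` list.
#' @export
sim_config <- function(region_length = 500000L, het_rate = 1e-3,
                       hom_rate = 0.6e-3, n_mosaic = 50L,
                       mosaic_mafs = c(0.1, 0.2, 0.3, 0.4),
                       coverage = 30, read_length = 150L,
                       insert_mean = 350, insert_sd = 50,
                       fragment_length_mean = 16176,
                       fragment_length_sd = 54387,
                       fragment_internal_coverage = 0.1,
                       base_error_rate = 0.002,
                       seed = 1L, chrom = "sim1") {
  stopifnot(
    region_length > 0, het_rate >= 0, het_rate < 1, hom_rate >= 0,
    n_mosaic >= 0, all(mosaic_mafs > 0), all(mosaic_mafs <= 0.5),
    coverage > 0, read_length > 0, fragment_length_mean > 0,
    fragment_internal_coverage > 0, base_error_rate >= 0
  )
  structure(
    list(
      region_length = as.integer(region_length), het_rate = het_rate,
      hom_rate = hom_rate, n_mosaic = as.integer(n_mosaic),
      mosaic_mafs = mosaic_mafs, coverage = coverage,
      read_length = as.integer(read_length),
      insert_mean = insert_mean, insert_sd = insert_sd,
      fragment_length_mean = fragment_length_mean,
      fragment_length_sd = fragment_length_sd,
      fragment_internal_coverage = fragment_internal_coverage,
      base_error_rate = base_error_rate,
      seed = as.integer(seed), chrom = chrom
    ),
    class = "sim_config"
  )
}

random_other_base <- function(base) {
  vapply(base, function(b) sample(setdiff(DNA_BASES, b), 1), character(1),
    USE.NAMES = FALSE
  )
}

#' Simulate a diploid genome with germline and mosaic truth
#'
#' Draws a random reference, places phased heterozygotes and homozygous-alt
#' sites by per-bp Bernoulli trials, builds the two haplotype sequences, and
#' places `n_mosaic` mosaic sites uniformly at homozygous-reference
#' positions at least 300 bp apart, each assigned to exactly one haplotype
#' and one allele fraction drawn from `mosaic_mafs`.
#'
#' @param cfg A [sim_config()].
#' @return A list: `reference`, `hap1`, `hap2` (character sequences),
#'   `truth` (list of `hets`, `homs`, `mosaic` tibbles), `cfg`.
#' @export
simulate_genome <- function(cfg = sim_config()) {
  set.seed(stage_seed(cfg$seed, "genome"))
  L <- cfg$region_length
  ref_chars <- sample(DNA_BASES, L, replace = TRUE)
  u <- runif(L)
  het_pos <- which(u < cfg$het_rate) - 1L
  hom_pos <- which(u >= cfg$het_rate & u < cfg$het_rate + cfg$hom_rate) - 1L
  het_ref <- ref_chars[het_pos + 1L]
  het_alt <- random_other_base(het_ref)
  alt_on_h1 <- runif(length(het_pos)) < 0.5
  hets <- tibble(
    chrom = cfg$chrom, pos = het_pos, ref = het_ref, alt = het_alt,
    h1 = ifelse(alt_on_h1, het_alt, het_ref),
    h2 = ifelse(alt_on_h1, het_ref, het_alt),
    phase_set = "ps1"
  )
  hom_ref <- ref_chars[hom_pos + 1L]
  homs <- tibble(
    chrom = cfg$chrom, pos = hom_pos, ref = hom_ref,
    alt = random_other_base(hom_ref)
  )
  hap1 <- hap2 <- ref_chars
  hap1[het_pos + 1L] <- hets$h1
  hap2[het_pos + 1L] <- hets$h2
  hap1[hom_pos + 1L] <- homs$alt
  hap2[hom_pos + 1L] <- homs$alt
  ## mosaic sites: hom-ref, pairwise >= 300 bp apart, away from variants
  taken <- c(het_pos, hom_pos)
  eligible <- setdiff(seq_len(L) - 1L, taken)
  chosen <- integer(0)
  pool <- sample(eligible)
  for (p in pool) {
    if (length(chosen) >= cfg$n_mosaic) break
    if (all(abs(chosen - p) >= 300L)) chosen <- c(chosen, p)
  }
  if (length(chosen) < cfg$n_mosaic) {
    abort(sprintf(
      "cannot place %d mosaic sites >=300 bp apart in %d bp", cfg$n_mosaic, L
    ))
  }
  chosen <- sort(chosen)
  mos_ref <- ref_chars[chosen + 1L]
  mosaic <- tibble(
    chrom = cfg$chrom, pos = chosen, ref = mos_ref,
    alt = random_other_base(mos_ref),
    haplotype = sample(c("H1", "H2"), length(chosen), replace = TRUE),
    maf = sample(cfg$mosaic_mafs, length(chosen), replace = TRUE)
  )
  list(
    reference = paste(ref_chars, collapse = ""),
    hap1 = paste(hap1, collapse = ""),
    hap2 = paste(hap2, collapse = ""),
    truth = list(hets = hets, homs = homs, mosaic = mosaic),
    cfg = cfg
  )
}

#' Simulate barcoded linked reads over a simulated genome
#'
#' Long fragments are drawn per haplotype with lognormal lengths
#' (parameterised to the configured mean and SD), placed uniformly, and
#' sequenced internally at `fragment_internal_coverage` by paired-end reads
#' with a unique barcode per fragment. A fragment on a mosaic site's
#' haplotype derives from the mutation-carrying cell lineage with
#' probability `2 * maf`, in which case every one of its reads covering the
#' site carries the mosaic allele — reads of one molecule come from one
#' cell, so they must agree. Base errors are i.i.d. substitutions. Reads
#' carry true coordinates (no aligner in the loop) and `BX` barcodes.
#'
#' The number of pairs emitted is calibrated so genome-wide depth
#' approaches `cfg$coverage` in the region interior.
#'
#' @param genome Result of [simulate_genome()].
#' @param cfg The same [sim_config()].
#' @return A list: `reads` (read tibble, coordinate-sorted),
#'   `read_truth` (tibble `read_name`, `fragment`, `true_hap`),
#'   `mosaic_support` (truth tibble with observed `alt_support` per site),
#'   `fragments_truth` (per-fragment haplotype/carrier table).
#' @export
simulate_linked_reads <- function(genome, cfg = genome$cfg) {
  set.seed(stage_seed(cfg$seed, "reads"))
  L <- cfg$region_length
  rl <- cfg$read_length
  m <- cfg$fragment_length_mean
  s <- cfg$fragment_length_sd
  sdlog <- sqrt(log(1 + (s / m)^2))
  meanlog <- log(m) - sdlog^2 / 2
  ## draw generously, then keep just enough fragments that the expected
  ## emitted read bases reach coverage * L (compensates for edge clipping
  ## and the heavy lognormal tail exceeding the region)
  target_bases <- cfg$coverage * L
  n_big <- ceiling(2.0 * target_bases / (cfg$fragment_internal_coverage * m)) + 100L
  flen <- pmax(round(stats::rlnorm(n_big, meanlog, sdlog)), rl)
  fstart <- floor(runif(n_big, -flen + 1, L))
  fs <- pmax(fstart, 0)
  fe <- pmin(fstart + flen, L)
  span <- fe - fs
  exp_bases <- cfg$fragment_internal_coverage * ifelse(span >= 2 * rl, span, 0)
  n_frag <- which(cumsum(exp_bases) >= target_bases)[1]
  if (is.na(n_frag)) n_frag <- n_big
  keep <- seq_len(n_frag)[span[seq_len(n_frag)] >= 2 * rl]
  frag <- tibble(
    fragment = sprintf("BX%07d-1", keep),
    hap = sample(1:2, n_frag, replace = TRUE)[keep],
    fs = as.integer(fs[keep]), fe = as.integer(fe[keep])
  )
  flen_k <- frag$fe - frag$fs
  n_pairs <- rpois(nrow(frag), cfg$fragment_internal_coverage * flen_k / (2 * rl))
  frag$n_pairs <- n_pairs
  ## carrier status per (fragment, mosaic site) on the matching haplotype
  mosaic <- genome$truth$mosaic
  carriers <- tibble(fragment = character(), pos = integer(), alt = character())
  if (nrow(mosaic)) {
    hits <- IRanges::findOverlaps(
      IRanges::IRanges(frag$fs + 1L, frag$fe),
      IRanges::IRanges(mosaic$pos + 1L, mosaic$pos + 1L)
    )
    fi <- S4Vectors::queryHits(hits)
    si <- S4Vectors::subjectHits(hits)
    same_hap <- frag$hap[fi] == ifelse(mosaic$haplotype[si] == "H1", 1L, 2L)
    carry <- same_hap & runif(length(fi)) < pmin(1, 2 * mosaic$maf[si])
    carriers <- tibble(
      fragment = frag$fragment[fi[carry]],
      pos = mosaic$pos[si[carry]],
      alt = mosaic$alt[si[carry]]
    )
  }
  ## expand read pairs
  pf <- frag[rep(seq_len(nrow(frag)), frag$n_pairs), ]
  if (nrow(pf) == 0) abort("simulation produced no reads; increase coverage or region")
  span <- pf$fe - pf$fs
  ins <- pmin(pmax(round(rnorm(nrow(pf), cfg$insert_mean, cfg$insert_sd)), 2 * rl), span)
  p0 <- pf$fs + floor(runif(nrow(pf)) * (span - ins + 1))
  pair_id <- paste0(pf$fragment, ":", sequence(frag$n_pairs))
  r1 <- tibble(
    pair_id = pair_id, fragment = pf$fragment, hap = pf$hap,
    start = as.integer(p0), end = as.integer(p0 + rl),
    is_reverse = FALSE, is_read1 = TRUE, mate_start = as.integer(p0 + ins - rl)
  )
  r2 <- tibble(
    pair_id = pair_id, fragment = pf$fragment, hap = pf$hap,
    start = as.integer(p0 + ins - rl), end = as.integer(p0 + ins),
    is_reverse = TRUE, is_read1 = FALSE, mate_start = as.integer(p0)
  )
  rd <- bind_rows(r1, r2)
  rd$read_name <- rd$pair_id
  ## sequence from the haplotype of origin (plain vector: cheap in-place edits)
  seqs <- rep(NA_character_, nrow(rd))
  for (h in 1:2) {
    idx <- which(rd$hap == h)
    hs <- if (h == 1) genome$hap1 else genome$hap2
    seqs[idx] <- substring(hs, rd$start[idx] + 1L, rd$end[idx])
  }
  ## mosaic edits: all reads of a carrier fragment covering the site
  if (nrow(carriers)) {
    ed <- dplyr::inner_join(
      dplyr::mutate(rd, .row = dplyr::row_number()),
      carriers,
      by = "fragment", relationship = "many-to-many"
    ) |>
      dplyr::filter(.data$pos >= .data$start, .data$pos < .data$end)
    if (nrow(ed)) {
      off <- ed$pos - ed$start + 1L
      for (k in seq_len(nrow(ed))) {
        substr(seqs[ed$.row[k]], off[k], off[k]) <- ed$alt[k]
      }
    }
  }
  ## i.i.d. base errors
  if (cfg$base_error_rate > 0) {
    n_err <- rbinom(nrow(rd), rl, cfg$base_error_rate)
    which_err <- which(n_err > 0)
    shift <- sample(1:3, sum(n_err), replace = TRUE) ## error base offset
    j <- 0L
    for (i in which_err) {
      s <- seqs[i]
      for (p in sample.int(rl, n_err[i])) {
        j <- j + 1L
        old <- substr(s, p, p)
        k <- match(old, DNA_BASES)
        new <- DNA_BASES[(if (is.na(k)) 0L else k - 1L + shift[j]) %% 4L + 1L]
        if (new == old) new <- DNA_BASES[k %% 4L + 1L]
        substr(s, p, p) <- new
      }
      seqs[i] <- s
    }
  }
  rd$seq <- seqs
  qual <- strrep(rawToChar(as.raw(37 + 33)), rl)
  reads <- tibble(
    read_name = rd$read_name,
    chrom = cfg$chrom,
    start = rd$start,
    end = rd$end,
    cigar = paste0(rl, "M"),
    seq = rd$seq,
    qual = qual,
    mapq = 60L,
    is_reverse = rd$is_reverse,
    is_duplicate = FALSE,
    is_secondary = FALSE,
    is_supplementary = FALSE,
    is_proper_pair = TRUE,
    is_read1 = rd$is_read1,
    mate_start = rd$mate_start,
    barcode = rd$fragment,
    hp_tag = NA_integer_,
    pair_id = rd$pair_id
  ) |> dplyr::arrange(.data$start, .data$read_name)
  read_truth <- tibble(
    read_name = rd$read_name,
    mate = ifelse(rd$is_read1, 1L, 2L),
    fragment = rd$fragment,
    true_hap = paste0("H", rd$hap)
  )
  ## observed alt support at each mosaic truth site, under count rules
  mosaic_support <- mosaic
  if (nrow(mosaic)) {
    det <- build_site_detail(reads, tibble(pos = mosaic$pos), genome$reference,
      fragments = NULL, min_mapq = 30, min_bq = 20,
      read_mm = integer(nrow(reads)) ## mismatch counts unused for support
    )
    sup <- det |>
      dplyr::mutate(alt = mosaic$alt[.data$site]) |>
      dplyr::group_by(.data$site) |>
      dplyr::summarise(alt_support = sum(.data$base == .data$alt), .groups = "drop")
    mosaic_support$alt_support <- 0L
    mosaic_support$alt_support[sup$site] <- as.integer(sup$alt_support)
  } else {
    mosaic_support$alt_support <- integer(0)
  }
  list(
    reads = reads,
    read_truth = read_truth,
    mosaic_support = mosaic_support,
    fragments_truth = dplyr::mutate(frag, true_hap = paste0("H", .data$hap)),
    carriers = carriers
  )
}

#' Resample deep independent coverage at chosen sites
#'
#' Emulates an orthogonal deep-sequencing validation assay (e.g. WES): at
#' each site the alternate-allele count is drawn as an independent
#' binomial at the stated depth, with the true allele fraction adjusted for
#' the base error rate.
#'
#' @param genome Result of [simulate_genome()].
#' @param sites Tibble with `chrom`, `pos` and optionally `alt`; true
#'   fractions are looked up in the genome truth (mosaic MAF, het 0.5,
#'   hom-alt 1, else 0).
#' @param depth Target depth per site.
#' @param cfg A [sim_config()] (for the error rate and seed).
#' @return Tibble `chrom`, `pos`, `depth`, `alt_count`, `alt`.
#' @export
simulate_deep_panel <- function(genome, sites, depth = 100L, cfg = genome$cfg) {
  set.seed(stage_seed(cfg$seed, "deep_panel"))
  tr <- genome$truth
  key <- function(df) paste(df$chrom, df$pos)
  p <- numeric(nrow(sites))
  alt <- if ("alt" %in% names(sites)) sites$alt else NA_character_
  mi <- match(key(sites), key(tr$mosaic))
  hi <- match(key(sites), key(tr$hets))
  oi <- match(key(sites), key(tr$homs))
  p[!is.na(mi)] <- tr$mosaic$maf[mi[!is.na(mi)]]
  p[!is.na(hi)] <- 0.5
  p[!is.na(oi)] <- 1
  alt <- dplyr::case_when(
    !is.na(mi) ~ tr$mosaic$alt[mi],
    !is.na(hi) ~ tr$hets$alt[hi],
    !is.na(oi) ~ tr$homs$alt[oi],
    TRUE ~ alt
  )
  e <- cfg$base_error_rate
  p_eff <- p * (1 - e) + (1 - p) * e / 3
  tibble(
    chrom = sites$chrom, pos = sites$pos,
    depth = as.integer(rep(depth, nrow(sites))),
    alt_count = rbinom(nrow(sites), depth, p_eff),
    alt = alt
  )
}

#' Write a simulated dataset to standard files
#'
#' Emits indexed BAM, reference FASTA, phased germline truth VCF, and a
#' mosaic truth TSV under `dir`.
#'
#' @param genome Result of [simulate_genome()].
#' @param sim Result of [simulate_linked_reads()].
#' @param dir Output directory (created if needed).
#' @return Named list of file paths.
#' @export
write_sim_dataset <- function(genome, sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cfg <- genome$cfg
  fa <- file.path(dir, "reference.fa")
  seqs <- Biostrings::DNAStringSet(genome$reference)
  names(seqs) <- cfg$chrom
  Biostrings::writeXStringSet(seqs, fa)
  bam <- file.path(dir, "reads.bam")
  write_bam(sim$reads, bam, setNames(cfg$region_length, cfg$chrom))
  vcf <- file.path(dir, "germline.vcf")
  write_phased_vcf(genome$truth$hets, vcf, homs = genome$truth$homs)
  truth_tsv <- file.path(dir, "mosaic_truth.tsv")
  utils::write.table(sim$mosaic_support, truth_tsv,
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  list(fasta = fa, bam = bam, vcf = vcf, mosaic_truth = truth_tsv)
}
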