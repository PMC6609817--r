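## hand-built reads and small cached simulations shared across test files

make_read <- function(name, start, seq, chrom = "chr1", barcode = NA_character_,
                      mapq = 60L, qual = NULL, cigar = NULL, is_reverse = FALSE,
                      is_duplicate = FALSE, is_secondary = FALSE,
                      is_supplementary = FALSE, is_proper_pair = TRUE,
                      is_read1 = TRUE, mate_start = NA_integer_,
                      pair_id = name) {
  if (is.null(qual)) qual <- strrep("J", nchar(seq)) ## phred 41
  if (is.null(cigar)) cigar <- paste0(nchar(seq), "M")
  tibble::tibble(
    read_name = name, chrom = chrom, start = as.integer(start),
    end = as.integer(start + GenomicAlignments::cigarWidthAlongReferenceSpace(cigar)),
    cigar = cigar, seq = seq, qual = qual, mapq = as.integer(mapq),
    is_reverse = is_reverse, is_duplicate = is_duplicate,
    is_secondary = is_secondary, is_supplementary = is_supplementary,
    is_proper_pair = is_proper_pair, is_read1 = is_read1,
    mate_start = as.integer(mate_start), barcode = barcode,
    hp_tag = NA_integer_, pair_id = pair_id
  )
}

make_hets <- function(pos, h1, h2, chrom = "chr1", phase_set = "ps1") {
  tibble::tibble(
    chrom = chrom, pos = as.integer(pos),
    ref = h1, alt = h2, h1 = h1, h2 = h2, phase_set = phase_set
  )
}

## cached small simulation: 120 kb, error-free unless noisy = TRUE
.sim_cache <- new.env(parent = emptyenv())

small_sim <- function(noisy = FALSE, seed = 42) {
  key <- paste0("s", noisy, seed)
  if (!is.null(.sim_cache[[key]])) return(.sim_cache[[key]])
  cfg <- sim_config(
    region_length = 120000L, het_rate = 1e-3, hom_rate = 0.6e-3,
    n_mosaic = 12L, mosaic_mafs = c(0.2, 0.3, 0.4), coverage = 30,
    base_error_rate = if (noisy) 0.002 else 0, seed = seed
  )
  g <- simulate_genome(cfg)
  sim <- simulate_linked_reads(g, cfg)
  germ <- dplyr::bind_rows(
    dplyr::transmute(g$truth$hets, chrom = chrom, pos = pos, ref = ref, alt = alt,
      genotype_class = "het", phased = TRUE),
    dplyr::transmute(g$truth$homs, chrom = chrom, pos = pos, ref = ref, alt = alt,
      genotype_class = "hom_alt", phased = FALSE)
  )
  out <- list(cfg = cfg, genome = g, sim = sim, germ = germ)
  .sim_cache[[key]] <- out
  out
}

## uniform random site-observation rows for predicate fuzzing
random_obs <- function(n, seed = 1) {
  set.seed(seed)
  depth <- sample(0:60, n, replace = TRUE)
  alt_count <- vapply(depth, function(d) sample(0:max(d, 0), 1), integer(1))
  tibble::tibble(
    chrom = "chr1",
    pos = sample.int(100000, n),
    ref = sample(c("A", "C", "G", "T"), n, replace = TRUE),
    alt = sample(c("A", "C", "G", "T", NA), n, replace = TRUE),
    depth = depth,
    alt_count = alt_count,
    maf = ifelse(depth > 0, alt_count / depth, 0),
    phased_fraction = round(runif(n), 3)
  )
}
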