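## independently coded brute-force oracles; deliberately naive loops so they
## share no code path with the package internals

oracle_group_fragments <- function(reads, max_gap) {
  groups <- list()
  bc <- ifelse(is.na(reads$barcode), paste0("..", seq_len(nrow(reads))), reads$barcode)
  for (key in unique(paste(reads$chrom, bc))) {
    idx <- which(paste(reads$chrom, bc) == key)
    idx <- idx[order(reads$start[idx], reads$end[idx])]
    cur <- idx[1]
    max_end <- reads$end[idx[1]]
    for (i in idx[-1]) {
      if (reads$start[i] - max_end > max_gap) {
        groups[[length(groups) + 1]] <- cur
        cur <- i
        max_end <- reads$end[i]
      } else {
        cur <- c(cur, i)
        max_end <- max(max_end, reads$end[i])
      }
    }
    groups[[length(groups) + 1]] <- cur
  }
  groups
}

## per-fragment haplotype vote recount: loops over hets and read bases
oracle_fragment_vote <- function(reads, hets, min_bq = 20) {
  v1 <- 0L
  v2 <- 0L
  for (h in seq_len(nrow(hets))) {
    best_bq <- -1L
    best_base <- NA_character_
    seen_pairs <- character(0)
    obs <- list()
    for (r in seq_len(nrow(reads))) {
      if (reads$is_duplicate[r] || reads$is_secondary[r] || reads$is_supplementary[r]) next
      p <- hets$pos[h]
      if (p < reads$start[r] || p >= reads$end[r]) next
      stopifnot(grepl("^[0-9]+M$", reads$cigar[r])) ## oracle fixtures are unclipped
      off <- p - reads$start[r] + 1L
      base <- substr(reads$seq[r], off, off)
      bq <- utf8ToInt(substr(reads$qual[r], off, off)) - 33L
      if (bq < min_bq) next
      obs[[length(obs) + 1]] <- list(pair = reads$pair_id[r], base = base, bq = bq)
    }
    if (!length(obs)) next
    ## one observation per pair, higher bq wins
    pairs <- unique(vapply(obs, `[[`, character(1), "pair"))
    for (pr in pairs) {
      sub <- Filter(function(o) o$pair == pr, obs)
      best <- sub[[which.max(vapply(sub, `[[`, numeric(1), "bq"))]]
      if (best$base == hets$h1[h]) v1 <- v1 + 1L
      if (best$base == hets$h2[h]) v2 <- v2 + 1L
    }
  }
  hap <- if (v1 > v2) "H1" else if (v2 > v1) "H2" else "unassigned"
  list(votes_h1 = v1, votes_h2 = v2, haplotype = hap)
}

## naive per-site counting from raw reads (vectorised pre-subset for speed,
## per-read logic stays a plain loop)
oracle_site_counts <- function(reads, pos, frag_hap, min_mapq = 30, min_bq = 20) {
  counts <- c(A = 0L, C = 0L, G = 0L, T = 0L)
  by_hap <- list(H1 = counts, H2 = counts, unassigned = counts)
  reads <- reads[reads$start <= pos & reads$end > pos, , drop = FALSE]
  for (r in seq_len(nrow(reads))) {
    if (reads$is_duplicate[r] || reads$is_secondary[r] || reads$is_supplementary[r]) next
    if (reads$mapq[r] < min_mapq) next
    if (pos < reads$start[r] || pos >= reads$end[r]) next
    off <- pos - reads$start[r] + 1L
    base <- substr(reads$seq[r], off, off)
    if (!base %in% names(counts)) next
    bq <- utf8ToInt(substr(reads$qual[r], off, off)) - 33L
    if (bq < min_bq) next
    counts[base] <- counts[base] + 1L
    hap <- frag_hap[[reads$fragment_id[r]]]
    if (is.null(hap) || !hap %in% c("H1", "H2")) hap <- "unassigned"
    by_hap[[hap]][base] <- by_hap[[hap]][base] + 1L
  }
  list(counts = counts, by_hap = by_hap)
}

oracle_site_filter <- function(obs, germ_keys, cfg, mode = "full") {
  out <- logical(nrow(obs))
  for (i in seq_len(nrow(obs))) {
    ok <- obs$depth[i] >= cfg$min_depth &&
      obs$alt_count[i] >= cfg$min_candidate_reads &&
      obs$maf[i] >= cfg$min_maf && obs$maf[i] <= cfg$max_maf &&
      !is.na(obs$alt[i])
    if (mode != "no_phasing" && obs$phased_fraction[i] < cfg$min_phased_fraction) ok <- FALSE
    if (cfg$exclude_germline && paste(obs$chrom[i], obs$pos[i]) %in% germ_keys) ok <- FALSE
    out[i] <- ok
  }
  out
}

oracle_in_mask <- function(mask, chrom, pos) {
  hit <- FALSE
  for (i in seq_len(nrow(mask))) {
    if (mask$chrom[i] == chrom && pos >= mask$start[i] && pos < mask$end[i]) hit <- TRUE
  }
  hit
}

oracle_alignment_filter <- function(clip_lens, n_mms, proper, in_homopolymer, cfg) {
  n <- length(clip_lens)
  if (n == 0) return(!in_homopolymer)
  a <- mean(clip_lens >= cfg$clip_len) > cfg$max_clip_frac
  b <- mean(pmax(n_mms - 1, 0)) > cfg$max_mean_mismatch
  c <- mean(!proper) > cfg$max_improper_frac
  !(a || b || c || in_homopolymer)
}

oracle_precision_recall <- function(call_keys, truth_keys) {
  tp <- sum(call_keys %in% truth_keys)
  fp <- length(call_keys) - tp
  found <- sum(truth_keys %in% call_keys)
  list(
    precision = if (length(call_keys)) tp / (tp + fp) else 0,
    recall = if (length(truth_keys)) found / length(truth_keys) else 0
  )
}
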