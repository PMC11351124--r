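# Shared fixtures and independent oracles, built in code at test time.

# a single valid record with controllable parts
toy_record <- function(id = "r1",
                       flank = paste(rep("C", 100), collapse = ""),
                       orf = paste0("ATG", strrep("GCA", 40), "TAA"),
                       label = NA_character_) {
  sorf_records(id, flank, orf, label = label)
}

# n valid records with random in-frame bodies (no feature signal implied)
toy_records <- function(n, n_codons = 40, seed = 1, label = NA_character_,
                        prefix = "r") {
  withr::with_seed(seed, {
    bases <- c("A", "C", "G", "T")
    sense <- setdiff(
      paste0(rep(bases, each = 16), rep(rep(bases, each = 4), 4),
             rep(bases, 16)),
      c("TAA", "TAG", "TGA"))
    flank <- vapply(seq_len(n), function(i)
      paste(sample(bases, 100, replace = TRUE), collapse = ""), character(1))
    orf <- vapply(seq_len(n), function(i)
      paste0("ATG",
             paste(sample(sense, n_codons, replace = TRUE), collapse = ""),
             "TAA"), character(1))
    sorf_records(sprintf("%s%04d", prefix, seq_len(n)), flank, orf,
                 label = label)
  })
}

write_fasta <- function(entries, path = tempfile(fileext = ".fasta")) {
  writeLines(unlist(lapply(names(entries), function(id)
    c(paste0(">", id), entries[[id]]))), path)
  path
}

# brute-force in-frame 3-mer tally, independent of codon_frequencies()
oracle_codon_freq <- function(window, normalized = TRUE) {
  bases <- c("A", "C", "G", "T")
  codons <- paste0(rep(bases, each = 16), rep(rep(bases, each = 4), 4),
                   rep(bases, 16))
  counts <- stats::setNames(numeric(64), codons)
  for (s in seq(1, nchar(window) - 2, by = 3)) {
    cod <- substr(window, s, s + 2)
    counts[cod] <- counts[cod] + 1
  }
  if (normalized) counts <- counts / (nchar(window) / 3)
  unname(counts)
}

# per-position code-table concatenation, independent of encode_tis()
oracle_tis_encode <- function(window9) {
  code <- list(A = c(0, 0, 0, 1), C = c(0, 0, 1, 0),
               G = c(1, 0, 0, 0), T = c(0, 1, 0, 0))
  unlist(lapply(strsplit(window9, "")[[1]], function(b) code[[b]]),
         use.names = FALSE)
}

random_inframe_window <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

# small calibrated model for predictor tests: trivially separable features
tiny_model_suite <- function(windows = c(54L, 99L, 180L), seed = 5) {
  cfg <- synthetic_config(n_pos = 60, n_neg = 60,
                          length_range_aa = c(62, 90))
  recs <- generate_labeled_set(cfg, seed = seed)
  sp <- split_dataset(recs, seed = seed)
  grid <- hyper_grid("svm", svm = list(kernel = "rbf", C = 1,
                                       gamma = "scale"))
  models <- list()
  for (w in windows) {
    fc <- feature_config(cc_window = w)
    ftr <- assemble_features(sp$train, fc)
    fva <- assemble_features(sp$validation, fc)
    ytr <- sp$train$label[match(ftr$meta$id, sp$train$id)]
    yva <- sp$validation$label[match(fva$meta$id, sp$validation$id)]
    fit <- train_final(ftr$features, ytr, grid[1, , drop = FALSE],
                       seed = seed, config = fc, window = w)
    models[[as.character(w)]] <- calibrate_platt(fit, fva$features, yva)
  }
  models
}
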