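#' Default human-like codon usage
#'
#' A synthetic default for the coding-body codon distribution of generated
#' positives: relative frequencies shaped like typical human codon usage
#' (e.g. strong CTG/GAG/CAG preference, rare TCG/CCG/ACG/GCG/CGT). These are
#' package defaults for simulation, not measurements from any particular
#' dataset.
#'
#' @return named numeric vector over the 61 sense codons summing to 1.
#' @export
default_codon_usage <- function() {
  per_thousand <- c(
    TTT = 17.6, TTC = 20.3, TTA = 7.7, TTG = 12.9, CTT = 13.2, CTC = 19.6,
    CTA = 7.2, CTG = 39.6, ATT = 16.0, ATC = 20.8, ATA = 7.5, ATG = 22.0,
    GTT = 11.0, GTC = 14.5, GTA = 7.1, GTG = 28.1, TCT = 15.2, TCC = 17.7,
    TCA = 12.2, TCG = 4.4, CCT = 17.5, CCC = 19.8, CCA = 16.9, CCG = 6.9,
    ACT = 13.1, ACC = 18.9, ACA = 15.1, ACG = 6.1, GCT = 18.4, GCC = 27.7,
    GCA = 15.8, GCG = 7.4, TAT = 12.2, TAC = 15.3, CAT = 10.9, CAC = 15.1,
    CAA = 12.3, CAG = 34.2, AAT = 17.0, AAC = 19.1, AAA = 24.4, AAG = 31.9,
    GAT = 21.8, GAC = 25.1, GAA = 29.0, GAG = 39.6, TGT = 10.6, TGC = 12.6,
    TGG = 13.2, CGT = 4.5, CGC = 10.4, CGA = 6.2, CGG = 11.4, AGT = 12.1,
    AGC = 19.5, AGA = 12.2, AGG = 12.0, GGT = 10.8, GGC = 22.2, GGA = 16.5,
    GGG = 16.5)
  u <- per_thousand[.SENSE_CODONS]
  u / sum(u)
}

#' Default Kozak-like TIS profile
#'
#' Position-specific nucleotide distributions for the 9 TIS positions
#' (-7..-1, +4, +5) of generated positives, modelled on the published
#' composition of vertebrate initiation contexts (gccRccATGG): a strong
#' purine preference at -3 (mostly A), G at +4, and the milder pyrimidine/C
#' bias elsewhere upstream. Synthetic defaults, not measurements of any
#' particular dataset.
#'
#' @return 9 x 4 matrix of probabilities (rows: positions -7..-1, +4, +5;
#'   columns A, C, G, T), each row summing to 1.
#' @export
default_kozak_profile <- function() {
  m <- matrix(c(
    # A     C     G     T
    0.20, 0.35, 0.22, 0.23,  # -7
    0.20, 0.35, 0.25, 0.20,  # -6
    0.22, 0.32, 0.24, 0.22,  # -5
    0.25, 0.30, 0.25, 0.20,  # -4
    0.60, 0.10, 0.25, 0.05,  # -3 strong purine (Kozak R)
    0.25, 0.40, 0.20, 0.15,  # -2
    0.22, 0.45, 0.23, 0.10,  # -1
    0.23, 0.16, 0.46, 0.15,  # +4 G of the Kozak consensus
    0.20, 0.30, 0.30, 0.20), # +5
    nrow = 9, byrow = TRUE,
    dimnames = list(c(as.character(-7:-1), "+4", "+5"), .BASES))
  m / rowSums(m)
}

#' Synthetic-data configuration
#'
#' Describes the generative contrast the classifier is meant to detect:
#' coding records carry biased codon usage in the ORF body and a Kozak-like
#' TIS context, non-coding records are ATG-anchored stretches of background
#' composition ending at the first in-frame stop. `signal_strength` mixes
#' the coding codon-usage model with the uniform distribution (1 = full
#' signal, 0 = indistinguishable from background).
#'
#' @param n_pos,n_neg number of coding / non-coding records to generate.
#' @param length_range_aa closed (min, max) protein length range in amino
#'   acids (ORF length / 3 - 1); default 20-100 aa spans the sORF regime
#'   across all three CC windows.
#' @param signal_strength mixing weight in `[0, 1]`.
#' @param codon_usage named probability vector over the 61 sense codons.
#' @param kozak_profile 9 x 4 position-specific nucleotide probabilities.
#' @param background length-4 base probabilities (A, C, G, T).
#' @param flank_length upstream flank length in nt.
#' @return a `synthetic_config` list.
#' @export
synthetic_config <- function(n_pos = 1000L, n_neg = 1000L,
                             length_range_aa = c(20L, 100L),
                             signal_strength = 1,
                             codon_usage = default_codon_usage(),
                             kozak_profile = default_kozak_profile(),
                             background = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25),
                             flank_length = 100L) {
  stopifnot(signal_strength >= 0, signal_strength <= 1,
            abs(sum(background) - 1) < 1e-9,
            abs(sum(codon_usage) - 1) < 1e-9,
            all(abs(rowSums(kozak_profile) - 1) < 1e-9),
            length_range_aa[1] >= 2L,
            length_range_aa[1] <= length_range_aa[2])
  structure(list(n_pos = as.integer(n_pos), n_neg = as.integer(n_neg),
                 length_range_aa = as.integer(length_range_aa),
                 signal_strength = signal_strength,
                 codon_usage = codon_usage[.SENSE_CODONS],
                 kozak_profile = kozak_profile,
                 background = background[.BASES],
                 flank_length = as.integer(flank_length)),
            class = "synthetic_config")
}

.sample_bases <- function(n, prob) {
  if (n == 0L) return(character(0))
  paste(sample(.BASES, n, replace = TRUE, prob = prob), collapse = "")
}

#' Generate labelled coding records
#'
#' Flanks are background sequence except the TIS positions (-7..-1 and the
#' two nucleotides after ATG at +4/+5), which are drawn from the
#' signal-weighted Kozak profile
#' `signal_strength * kozak + (1 - signal_strength) * background`;
#' body codons are i.i.d. from the mixture
#' `signal_strength * codon_usage + (1 - signal_strength) * uniform`;
#' the ORF ends with a uniformly chosen stop codon. At `signal_strength = 0`
#' coding records are therefore statistically indistinguishable from the
#' non-coding background in both feature families. Should the Kozak draw at
#' +4/+5 turn the first body codon into a stop, its third base is redrawn.
#'
#' @param n number of records.
#' @param config a [synthetic_config()].
#' @param seed RNG seed.
#' @return `sorf_records` labelled `"coding"`.
#' @export
generate_coding_records <- function(n, config = synthetic_config(),
                                    seed = 1L) {
  .with_seed(seed, {
    amin <- config$length_range_aa[1]; amax <- config$length_range_aa[2]
    aa <- sample(amin:amax, n, replace = TRUE)
    k <- aa - 1L # body codons between start and stop
    mix <- config$signal_strength * config$codon_usage +
      (1 - config$signal_strength) / length(.SENSE_CODONS)
    body_all <- sample(.SENSE_CODONS, sum(k), replace = TRUE, prob = mix)
    ends <- cumsum(k)
    starts <- ends - k + 1L
    stops <- sample(.STOP_CODONS, n, replace = TRUE)

    fl <- config$flank_length
    flank <- vapply(seq_len(n), function(i) .sample_bases(fl, config$background),
                    character(1))
    profile <- config$signal_strength * config$kozak_profile +
      (1 - config$signal_strength) * rep(config$background, each = 9L)
    kz <- apply(profile, 1L,
                function(p) sample(.BASES, n, replace = TRUE, prob = p))
    kz <- matrix(kz, nrow = n)
    # overwrite the last 7 flank nt with the upstream Kozak positions
    substr(flank, fl - 6L, fl) <- apply(kz[, 1:7, drop = FALSE], 1L, paste,
                                        collapse = "")
    orf <- character(n)
    for (i in seq_len(n)) {
      body <- body_all[starts[i]:ends[i]]
      first <- paste0(kz[i, 8L], kz[i, 9L], substr(body[1L], 3L, 3L))
      while (first %in% .STOP_CODONS) # rare: Kozak +4/+5 created a stop
        first <- paste0(kz[i, 8L], kz[i, 9L],
                        sample(.BASES, 1L, prob = config$background))
      body[1L] <- first
      orf[i] <- paste0("ATG", paste(body, collapse = ""), stops[i])
    }
    sorf_records(sprintf("pos_%05d", seq_len(n)), flank, orf, label = "coding")
  })
}

#' Generate labelled non-coding records
#'
#' Emulates ATG-anchored background pseudo-ORFs: under per-base background
#' composition, the body-codon count follows a geometric law with per-codon
#' stop probability `p_stop`; the record is constrained to the configured
#' length range. Sampling is performed directly from the range-truncated
#' geometric with body codons i.i.d. from the background codon distribution
#' conditioned on non-stop and the terminal stop from the stop-conditioned
#' distribution — exactly the distribution of draw-until-stop with rejection
#' of out-of-range lengths, without the unbounded retries. Flanks are pure
#' background.
#'
#' @inheritParams generate_coding_records
#' @return `sorf_records` labelled `"noncoding"`.
#' @export
generate_noncoding_records <- function(n, config = synthetic_config(),
                                       seed = 1L) {
  base_p <- config$background
  codons <- .codon_order()
  codon_p <- apply(do.call(rbind, strsplit(codons, "")), 1L,
                   function(b) prod(base_p[b]))
  names(codon_p) <- codons
  p_stop <- sum(codon_p[.STOP_CODONS])
  if (p_stop <= 0)
    stop("generation error: background composition admits no stop codon")
  sense_p <- codon_p[.SENSE_CODONS] / (1 - p_stop)
  stop_p <- codon_p[.STOP_CODONS] / p_stop

  .with_seed(seed, {
    amin <- config$length_range_aa[1]; amax <- config$length_range_aa[2]
    krange <- (amin - 1L):(amax - 1L)
    kprob <- (1 - p_stop)^krange * p_stop # truncated geometric weights
    k <- sample(krange, n, replace = TRUE, prob = kprob)
    body_all <- sample(.SENSE_CODONS, sum(k), replace = TRUE, prob = sense_p)
    ends <- cumsum(k); starts <- ends - k + 1L
    stops <- sample(.STOP_CODONS, n, replace = TRUE, prob = stop_p)
    orf <- vapply(seq_len(n), function(i)
      paste0("ATG", paste(body_all[starts[i]:ends[i]], collapse = ""), stops[i]),
      character(1))
    flank <- vapply(seq_len(n), function(i)
      .sample_bases(config$flank_length, base_p), character(1))
    sorf_records(sprintf("neg_%05d", seq_len(n)), flank, orf,
                 label = "noncoding")
  })
}

#' Generate a balanced/unbalanced labelled set
#'
#' Convenience wrapper drawing `config$n_pos` coding and `config$n_neg`
#' non-coding records with sub-seeds derived from `seed`.
#'
#' @param config a [synthetic_config()].
#' @param seed RNG seed.
#' @return `sorf_records` with both labels.
#' @export
generate_labeled_set <- function(config = synthetic_config(), seed = 1L) {
  pos <- generate_coding_records(config$n_pos, config, seed = seed)
  neg <- generate_noncoding_records(config$n_neg, config, seed = seed + 1L)
  out <- rbind(pos, neg)
  rownames(out) <- NULL
  class(out) <- c("sorf_records", "data.frame")
  out
}

#' Generate a mini-genome with planted genes
#'
#' Builds a single contig alternating background intergenic stretches with
#' embedded coding genes (`intergenic[1]`, `gene[1]`, `intergenic[2]`, ...,
#' `gene[n]`), plus a truth manifest of every planted feature, so interval
#' logic (intergenic complement, promoter masking, size-class partitioning)
#' can be asserted against known truth.
#'
#' @param intergenic_lengths integer vector of intergenic stretch lengths
#'   (nt); one gene is planted after each of the first `n_genes` stretches.
#' @param config a [synthetic_config()] (gene sequences are generated as
#'   coding records).
#' @param n_genes number of genes to plant (default: one per stretch; 0
#'   yields a purely intergenic contig).
#' @param seed RNG seed.
#' @param contig contig name.
#' @return list with `annotation` (a [genome_annotation()]), `manifest`
#'   (data frame of planted features: type, start, end 1-based closed) and
#'   `records` (the planted coding records).
#' @export
generate_minigenome <- function(intergenic_lengths, config = synthetic_config(),
                                n_genes = length(intergenic_lengths),
                                seed = 1L, contig = "chrS") {
  stopifnot(n_genes <= length(intergenic_lengths))
  genes <- generate_coding_records(max(n_genes, 1L), config, seed = seed)
  genes <- genes[seq_len(n_genes), , drop = FALSE]
  inter <- .with_seed(seed + 1L, vapply(intergenic_lengths, function(L)
    .sample_bases(L, config$background), character(1)))
  pieces <- character(0)
  manifest <- data.frame(type = character(), id = character(),
                         start = integer(), end = integer(),
                         stringsAsFactors = FALSE)
  pos <- 0L
  for (i in seq_along(intergenic_lengths)) {
    pieces <- c(pieces, inter[i])
    manifest <- rbind(manifest, data.frame(
      type = "intergenic", id = sprintf("intergenic_%d", i),
      start = pos + 1L, end = pos + nchar(inter[i]),
      stringsAsFactors = FALSE))
    pos <- pos + nchar(inter[i])
    if (i > n_genes) next
    gene_seq <- genes$orf[i]
    pieces <- c(pieces, gene_seq)
    manifest <- rbind(manifest, data.frame(
      type = "gene", id = genes$id[i],
      start = pos + 1L, end = pos + nchar(gene_seq),
      stringsAsFactors = FALSE))
    pos <- pos + nchar(gene_seq)
  }
  genome <- Biostrings::DNAStringSet(stats::setNames(paste(pieces, collapse = ""),
                                                     contig))
  gm <- manifest[manifest$type == "gene", ]
  gr <- GenomicRanges::GRanges(rep(contig, nrow(gm)),
                               IRanges::IRanges(gm$start, gm$end),
                               strand = rep("+", nrow(gm)))
  list(annotation = genome_annotation(genome, gr), manifest = manifest,
       records = genes)
}
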