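#' Negative-sampling configuration
#'
#' Parameters for constructing intergenic pseudo-ORF negatives: promoters
#' (2000 nt upstream of each gene) are masked out of the intergenic space;
#' regions of 20-50 kb feed the training pool and regions over 50 kb the
#' simulated-evaluation pool; ATG-anchored candidates extended to the first
#' in-frame stop are kept when their length falls within `length_bounds`.
#' The default bounds (60, 450) nt give pseudo-ORFs with a mean length near
#' 210 nt over near-random sequence; the achieved mean is reported so the
#' bounds can be tuned.
#'
#' @param promoter_mask nt masked upstream of each gene (default 2000).
#' @param training_size_class closed length interval (nt) of intergenic
#'   regions used for training negatives.
#' @param n_train number of training negatives to draw (default 8100).
#' @param target_mean_length informational target mean pseudo-ORF length.
#' @param length_bounds closed (min, max) pseudo-ORF length bounds in nt.
#' @param flank_length upstream flank to attach (truncated at interval
#'   boundaries).
#' @return a `negative_sampling_config` list.
#' @export
negative_sampling_config <- function(promoter_mask = 2000L,
                                     training_size_class = c(20000L, 50000L),
                                     n_train = 8100L,
                                     target_mean_length = 210L,
                                     length_bounds = c(60L, 450L),
                                     flank_length = 100L) {
  stopifnot(length_bounds[1] >= 60L, length_bounds[1] <= length_bounds[2])
  structure(list(promoter_mask = as.integer(promoter_mask),
                 training_size_class = as.integer(training_size_class),
                 n_train = as.integer(n_train),
                 target_mean_length = as.integer(target_mean_length),
                 length_bounds = as.integer(length_bounds),
                 flank_length = as.integer(flank_length)),
            class = "negative_sampling_config")
}

#' Intergenic complement with promoter masking
#'
#' Complements the union of gene intervals per contig, then removes
#' `promoter_mask` nt immediately upstream (strand-aware) of every gene from
#' the remaining space; returns maximal disjoint intervals.
#'
#' @param annotation a [genome_annotation()].
#' @param promoter_mask nt to mask upstream of each gene.
#' @return `GRanges` of intergenic intervals.
#' @export
compute_intergenic_regions <- function(annotation, promoter_mask = 2000L) {
  genes <- annotation$genes
  sl <- GenomeInfoDb::seqlengths(genes)
  contigs <- GenomicRanges::GRanges(names(sl),
                                    IRanges::IRanges(1L, unname(sl)))
  GenomeInfoDb::seqlevels(contigs) <- GenomeInfoDb::seqlevels(genes)
  GenomeInfoDb::seqlengths(contigs) <- sl
  if (length(genes) == 0L) {
    warning("annotation has no genes; whole contigs are intergenic")
    return(contigs)
  }
  genic <- GenomicRanges::reduce(genes, ignore.strand = TRUE)
  inter <- GenomicRanges::setdiff(contigs, genic, ignore.strand = TRUE)
  prom <- GenomicRanges::trim(
    GenomicRanges::promoters(genes, upstream = promoter_mask, downstream = 0L))
  inter <- GenomicRanges::setdiff(inter, prom, ignore.strand = TRUE)
  GenomicRanges::reduce(inter)
}

#' Partition intergenic intervals by size class
#'
#' Training pool: lengths within the closed interval `size_class` (default
#' 20-50 kb); simulated pool: lengths strictly greater than the upper bound.
#' The pools are disjoint by construction.
#'
#' @param intergenic `GRanges` of disjoint intergenic intervals.
#' @param size_class closed (min, max) length bounds in nt for the training
#'   pool.
#' @return list with `GRanges` elements `training_pool` and `simulated_pool`.
#' @export
partition_by_size <- function(intergenic, size_class = c(20000L, 50000L)) {
  w <- BiocGenerics::width(intergenic)
  training <- intergenic[w >= size_class[1] & w <= size_class[2]]
  simulated <- intergenic[w > size_class[2]]
  if (length(training) == 0L && length(simulated) == 0L)
    warning("no intergenic interval reaches the training size class")
  list(training_pool = training, simulated_pool = simulated)
}

# all ATG-anchored pseudo-ORFs (first in-frame stop, closed length bounds)
# within one sequence; returns 1-based start/end of ATG..stop
.scan_pseudo_orfs <- function(seqchar, length_bounds) {
  atg <- gregexpr("ATG", seqchar, fixed = TRUE)[[1]]
  if (atg[1] == -1L) return(data.frame(start = integer(), end = integer()))
  atg <- as.integer(atg)
  n <- nchar(seqchar)
  codon_start <- seq.int(1L, n - 2L)
  is_stop <- substring(seqchar, codon_start, codon_start + 2L) %in% .STOP_CODONS
  stop_pos <- which(is_stop)
  res_start <- integer(0); res_end <- integer(0)
  for (f in 0:2) {
    a <- atg[(atg - 1L) %% 3L == f]
    s <- stop_pos[(stop_pos - 1L) %% 3L == f]
    if (!length(a) || !length(s)) next
    # first in-frame stop strictly downstream of the ATG codon
    idx <- findInterval(a + 2L, s) + 1L
    ok <- idx <= length(s)
    a <- a[ok]; idx <- idx[ok]
    end <- s[idx] + 2L
    len <- end - a + 1L
    keep <- len >= length_bounds[1] & len <= length_bounds[2]
    res_start <- c(res_start, a[keep]); res_end <- c(res_end, end[keep])
  }
  o <- order(res_start, res_end)
  data.frame(start = res_start[o], end = res_end[o])
}

#' Sample intergenic pseudo-ORF negatives
#'
#' Scans the pooled intervals (+ strand) for ATG occurrences, extends each to
#' the first in-frame stop codon, keeps candidates whose total length lies
#' within `config$length_bounds`, and samples `n` without replacement under
#' the given seed. The upstream flank (up to `config$flank_length` nt,
#' truncated at the interval boundary) is attached. The achieved mean length
#' is reported via message and the `"achieved_mean_length"` attribute.
#'
#' @param pool `GRanges` of intergenic intervals to sample from.
#' @param genome named `DNAStringSet` (or character) of contig sequences.
#' @param n number of negatives to draw.
#' @param config a [negative_sampling_config()].
#' @param seed RNG seed for reproducible sampling.
#' @return `sorf_records` labelled `"noncoding"`.
#' @export
sample_negative_orfs <- function(pool, genome, n,
                                 config = negative_sampling_config(),
                                 seed = 1L) {
  if (length(pool) == 0L) stop("empty interval pool")
  if (!methods::is(genome, "DNAStringSet"))
    genome <- Biostrings::DNAStringSet(genome)
  cand <- list()
  for (i in seq_along(pool)) {
    contig <- as.character(GenomeInfoDb::seqnames(pool)[i])
    s0 <- GenomicRanges::start(pool)[i]
    e0 <- GenomicRanges::end(pool)[i]
    seqchar <- as.character(Biostrings::subseq(genome[[contig]], s0, e0))
    hits <- .scan_pseudo_orfs(seqchar, config$length_bounds)
    if (nrow(hits) == 0L) next
    flank_start <- pmax(1L, hits$start - config$flank_length)
    cand[[length(cand) + 1L]] <- data.frame(
      contig = contig,
      start = s0 + hits$start - 1L, end = s0 + hits$end - 1L,
      orf = substring(seqchar, hits$start, hits$end),
      flank = substring(seqchar, flank_start, hits$start - 1L),
      stringsAsFactors = FALSE)
  }
  if (!length(cand)) {
    warning("no pseudo-ORF candidate found in the pool")
    return(sorf_records(character(), character(), character()))
  }
  cand <- do.call(rbind, cand)
  if (nrow(cand) < n) {
    warning(sprintf("only %d candidates for %d requested; returning all",
                    nrow(cand), n))
    take <- seq_len(nrow(cand))
  } else {
    take <- .with_seed(seed, sample.int(nrow(cand), n))
    take <- sort(take)
  }
  picked <- cand[take, , drop = FALSE]
  recs <- sorf_records(
    id = sprintf("neg_%s_%d_%d", picked$contig, picked$start, picked$end),
    flank = picked$flank, orf = picked$orf, label = "noncoding")
  mean_len <- mean(nchar(recs$orf))
  message(sprintf("sampled %d negatives; achieved mean length %.1f nt",
                  nrow(recs), mean_len))
  attr(recs, "achieved_mean_length") <- mean_len
  attr(recs, "n_candidates") <- nrow(cand)
  recs
}

#' Build positive record sets from a CDS FASTA and isoform metadata
#'
#' Genes with exactly one isoform form the training positives (avoiding
#' alternative start-site ambiguity); for multi-isoform genes only the
#' longest isoform enters the simulated-evaluation positives (ties broken by
#' lexicographically smallest record id). The two sets are disjoint by gene.
#' Records without metadata are excluded with a report entry.
#'
#' @param records `sorf_records` read from the CDS FASTA (flank + CDS).
#' @param metadata data frame with columns `record_id`, `gene_id`,
#'   `isoform_count`.
#' @return list with `training_records`, `simulated_records` (both labelled
#'   `"coding"`) and `excluded` (data frame `id`, `reason`).
#' @export
build_positive_records <- function(records, metadata) {
  stopifnot(all(c("record_id", "gene_id", "isoform_count") %in% names(metadata)))
  m <- match(records$id, metadata$record_id)
  excluded <- data.frame(id = records$id[is.na(m)],
                         reason = rep("no metadata", sum(is.na(m))),
                         stringsAsFactors = FALSE)
  keep <- !is.na(m)
  recs <- records[keep, , drop = FALSE]
  gene <- metadata$gene_id[m[keep]]
  iso <- metadata$isoform_count[m[keep]]
  recs$label <- "coding"

  training <- recs[iso == 1L, , drop = FALSE]
  multi <- recs[iso > 1L, , drop = FALSE]
  multi_gene <- gene[iso > 1L]
  sim_idx <- integer(0)
  if (nrow(multi)) {
    o <- order(multi_gene, -nchar(multi$orf), multi$id)
    first <- !duplicated(multi_gene[o])
    sim_idx <- o[first]
  }
  simulated <- multi[sim_idx, , drop = FALSE]
  rownames(training) <- rownames(simulated) <- NULL
  class(training) <- class(simulated) <- c("sorf_records", "data.frame")
  list(training_records = training, simulated_records = simulated,
       excluded = excluded)
}

#' Stratified train/validation/test split
#'
#' Splits labelled records 60/20/20 by default, stratified by label;
#' validation and test sizes are floor-allocated per class with remainders
#' going to the training split. Reproducible under a fixed seed.
#'
#' @param records labelled `sorf_records`.
#' @param ratios `(train, validation, test)` ratios summing to 1.
#' @param seed RNG seed.
#' @return list of `sorf_records`: `train`, `validation`, `test`.
#' @export
split_dataset <- function(records, ratios = c(0.6, 0.2, 0.2), seed = 1L) {
  stopifnot(abs(sum(ratios) - 1) < 1e-9)
  if (anyNA(records$label)) stop("all records must carry a label")
  counts <- table(records$label)
  if (any(counts < 3L))
    stop("cannot stratify: class with fewer than 3 members")
  assign_split <- rep(NA_character_, nrow(records))
  .with_seed(seed, {
    for (cl in names(counts)) {
      idx <- which(records$label == cl)
      n <- length(idx)
      n_val <- floor(ratios[2] * n)
      n_test <- floor(ratios[3] * n)
      perm <- sample(idx)
      assign_split[perm[seq_len(n_val)]] <- "validation"
      assign_split[perm[n_val + seq_len(n_test)]] <- "test"
      assign_split[perm[(n_val + n_test + 1):n]] <- "train"
    }
  })
  out <- lapply(c(train = "train", validation = "validation", test = "test"),
                function(s) {
                  r <- records[assign_split == s, , drop = FALSE]
                  rownames(r) <- NULL
                  class(r) <- c("sorf_records", "data.frame")
                  r
                })
  out
}
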