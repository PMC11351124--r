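# base alphabet used throughout; order fixes the lexicographic codon order
.BASES <- c("A", "C", "G", "T")
.STOP_CODONS <- c("TAA", "TAG", "TGA")

# AAA, AAC, ..., TTT (lexicographic over A < C < G < T)
.codon_order <- function() {
  paste0(rep(.BASES, each = 16L),
         rep(rep(.BASES, each = 4L), times = 4L),
         rep(.BASES, times = 16L))
}

.SENSE_CODONS <- setdiff(.codon_order(), .STOP_CODONS)

.ANNOTATION_CLASSES <- c("exonic", "intronic", "intergenic", "lncRNA",
                         "3UTR", "5UTR", "ensembl_sORF", "NMD", "TEC",
                         "NSD", "pseudogene")

# md5 fingerprint of an arbitrary character vector (offline-safe; no digest
# package in the stack, so hash through a temp file)
.fingerprint <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(as.character(x), f)
  unname(tools::md5sum(f))
}

# run code under a private RNG state seeded with `seed`
.with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    on.exit({
      if (is.null(old)) rm(".Random.seed", envir = globalenv())
      else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(code)
}
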