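# Small deterministic fixtures shared across test files.

toyGenome <- function() {
  Genome(c("chr1", "chr2", "chrX"), c(3e7, 2e7, 1.5e7), species = "toy")
}

# two-chromosome genome with an exactly known bin layout
miniGenome <- function() {
  Genome(c("chr1", "chr2"), c(1e7, 5.5e6), species = "mini")
}

# hand-built track: values assigned directly on a BinIndex
handTrack <- function(binIndex, values) {
  new("CompartmentTrack", binIndex = binIndex, values = values,
      truth = rep(NA_character_, length(values)),
      dynamicUp = integer(0), dynamicDown = integer(0))
}

# minimal ContactSet from a position table
handCell <- function(df, genome, id = "cell1", ...) {
  new("ContactSet", cellId = id, donor = NA_character_, age = NA_real_,
      ageUnit = "years", sex = NA_character_, species = genome@species,
      contacts = canonicalizeContacts(df, genome), truth = list(), ...)
}

contactDF <- function(chromA, posA, chromB, posB) {
  data.frame(chromA = chromA, posA = posA, chromB = chromB, posB = posB,
             stringsAsFactors = FALSE)
}
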