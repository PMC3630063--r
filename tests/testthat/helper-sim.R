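# Shared fixture builders. Small configurations keep unit tests fast;
# the acceptance suite uses the default study conditions.

smallConfig <- function(seed = 1L, ...) {
  defaults <- list(seed = seed, nScaffolds = 1L, scaffoldLength = 15000L,
                   nHairpins = 5L, nTranscripts = 6L, readDepth = 6000L,
                   degradomeDepth = 3000L)
  do.call(SimulationConfig, utils::modifyList(defaults, list(...)))
}

# a TagSet built directly from sequences and counts
makeTags <- function(seqs, control = 1L, drought = 0L) {
  TagSet(data.frame(seq = asRna(seqs), count = rep_len(control, length(seqs))),
         data.frame(seq = asRna(seqs), count = rep_len(drought, length(seqs))))
}

randomDnaString <- function(n, seed) {
  set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# FASTQ data.frame from inserts (+ optional adapter), uniform quality
fastqFrom <- function(inserts, adapter = "", qual = "I") {
  seqs <- paste0(chartr("U", "T", toupper(inserts)), adapter)
  data.frame(id = sprintf("r%03d", seq_along(seqs)), seq = seqs,
             qual = strrep(qual, nchar(seqs)))
}
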