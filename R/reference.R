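#' Generate a synthetic reference sequence
#'
#' Produces a random haploid reference over ACGT used as the source of
#' trinucleotide context for synthetic cohorts. A single chromosome with
#' 1-based coordinates stands in for a genome at desk scale.
#'
#' @param genome_length total length in bases (>= 1e4).
#' @param seed integer seed; the sequence is deterministic given the seed.
#' @param base_probs length-4 probability vector over A, C, G, T.
#' @return character scalar of length `genome_length`.
#' @export
generate_reference <- function(genome_length, seed,
                               base_probs = rep(0.25, 4)) {
  if (!is.numeric(genome_length) || length(genome_length) != 1 ||
      is.na(genome_length) || genome_length < 1e4) {
    stop("genome_length must be a single number >= 1e4")
  }
  stopifnot(length(base_probs) == 4, all(base_probs >= 0),
            abs(sum(base_probs) - 1) < 1e-9)
  old <- .Random.seed_guard(seed)
  on.exit(old(), add = TRUE)
  paste(sample(BASES, genome_length, replace = TRUE, prob = base_probs),
        collapse = "")
}

# Set the RNG to a given seed and return a restorer function, so library
# functions do not permanently disturb the caller's RNG stream.
.Random.seed_guard <- function(seed) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  saved <- if (has_seed) get(".Random.seed", envir = globalenv()) else NULL
  if (!is.null(seed)) set.seed(seed)
  function() {
    if (!is.null(saved)) {
      assign(".Random.seed", saved, envir = globalenv())
    }
    invisible(NULL)
  }
}

#' Split a reference string into a base vector
#' @keywords internal
#' @noRd
.ref_bases <- function(reference) strsplit(reference, "")[[1]]

#' Index reference positions by pyrimidine-strand trinucleotide context
#'
#' For every internal position (2 .. L-1) computes the pyrimidine-oriented
#' trinucleotide centred there and returns, per context, the positions at
#' which it occurs. Mutations drawn from a 96-channel signature are placed by
#' sampling from the pool matching the drawn channel's context.
#'
#' @param reference character scalar (the genome).
#' @return list: `pools` (named list context -> integer positions),
#'   `bases` (character vector of bases), `length`.
#' @export
context_index <- function(reference) {
  b <- .ref_bases(reference)
  L <- length(b)
  centre <- b[2:(L - 1)]
  tri <- paste0(b[1:(L - 2)], centre, b[3:L])
  flip <- centre %in% PURINES
  tri[flip] <- revcomp(tri[flip])
  pools <- split(2:(L - 1), tri)
  list(pools = pools, bases = b, length = L)
}

#' Trinucleotide context at given positions
#'
#' @param reference character scalar genome.
#' @param pos integer positions (must lie in 2 .. L-1).
#' @return character vector of forward-strand trinucleotides.
#' @export
trinucleotide_at <- function(reference, pos) {
  L <- nchar(reference)
  if (any(pos < 2 | pos > L - 1)) stop("positions must lie in 2 .. L-1")
  substring(reference, pos - 1, pos + 1)
}

#' Write a reference to FASTA
#'
#' @param reference character scalar genome.
#' @param path output file path.
#' @param name sequence name.
#' @return `path`, invisibly.
#' @export
write_reference_fasta <- function(reference, path, name = "chr1") {
  seqs <- Biostrings::DNAStringSet(reference)
  names(seqs) <- name
  Biostrings::writeXStringSet(seqs, filepath = path)
  invisible(path)
}

#' Read a single-sequence FASTA back into a plain string
#'
#' @param path FASTA file path.
#' @return character scalar.
#' @export
read_reference_fasta <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  as.character(seqs[[1]])
}
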