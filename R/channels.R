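#' @keywords internal
"_PACKAGE"

BASES <- c("A", "C", "G", "T")
PYRIMIDINES <- c("C", "T")
PURINES <- c("A", "G")

COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

#' Reverse complement of a base vector or short string vector
#'
#' Vectorised over its input; each element is a DNA string over ACGT.
#'
#' @param x character vector of DNA strings.
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  vapply(strsplit(x, ""), function(b) {
    paste(rev(unname(COMPLEMENT[b])), collapse = "")
  }, character(1))
}

#' The 96 single-base-substitution channels
#'
#' Channels are indexed on the pyrimidine strand in COSMIC order: substitution
#' classes C>A, C>G, C>T, T>A, T>C, T>G, each across the 16 flanking-base
#' combinations, named like `"A[C>A]A"`.
#'
#' @return data.frame with columns `channel`, `context` (trinucleotide),
#'   `ref`, `alt`, `five`, `three`.
#' @export
sbs_channels <- function() {
  subs <- rbind(
    c("C", "A"), c("C", "G"), c("C", "T"),
    c("T", "A"), c("T", "C"), c("T", "G")
  )
  out <- do.call(rbind, lapply(seq_len(nrow(subs)), function(i) {
    ref <- subs[i, 1]; alt <- subs[i, 2]
    grid <- expand.grid(five = BASES, three = BASES,
                        stringsAsFactors = FALSE)
    grid <- grid[order(grid$five, grid$three), ]
    data.frame(
      channel = paste0(grid$five, "[", ref, ">", alt, "]", grid$three),
      context = paste0(grid$five, ref, grid$three),
      ref = ref, alt = alt,
      five = grid$five, three = grid$three,
      stringsAsFactors = FALSE
    )
  }))
  rownames(out) <- out$channel
  out
}

#' Normalize a (trinucleotide, ref, alt) triple onto the pyrimidine strand
#'
#' Purine-reference mutations are reverse-complemented so the mutated base is
#' a pyrimidine; pyrimidine-reference mutations pass through unchanged.
#'
#' @param context character vector of trinucleotides centred on the ref base.
#' @param ref,alt character vectors of single bases.
#' @return data.frame with pyrimidine-strand `context`, `ref`, `alt` and the
#'   corresponding `channel` name.
#' @export
pyrimidine_orient <- function(context, ref, alt) {
  stopifnot(length(context) == length(ref), length(ref) == length(alt))
  flip <- ref %in% PURINES
  context[flip] <- revcomp(context[flip])
  ref[flip] <- unname(COMPLEMENT[ref[flip]])
  alt[flip] <- unname(COMPLEMENT[alt[flip]])
  channel <- paste0(substr(context, 1, 1), "[", ref, ">", alt, "]",
                    substr(context, 3, 3))
  data.frame(context = context, ref = ref, alt = alt, channel = channel,
             stringsAsFactors = FALSE)
}

#' Cosine similarity between two non-negative vectors
#'
#' @param a,b numeric vectors of equal length, non-negative, not both zero.
#' @return similarity in `[0, 1]`.
#' @export
cosine <- function(a, b) {
  stopifnot(length(a) == length(b))
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) stop("cosine undefined for a zero vector")
  sum(a * b) / (na * nb)
}
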