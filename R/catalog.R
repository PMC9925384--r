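# Synthetic reference-signature catalog.
#
# The pipeline attributes spectra against a user-supplied catalog (COSMIC v3
# vectors for real analyses). The catalog shipped here is SYNTHETIC: peak-based
# approximations that preserve the qualitative character of each signature
# (SBS1 NCG>NTG clock, SBS2 TCN>TTN and SBS13 TCN>TGN APOBEC, flat SBS5/SBS40,
# SBS18 C>A oxidative, SBS17b T>G, SBS35 platinum-like, SBS41, SBS88
# colibactin-like) while keeping pairs separable at desk scale. It is data,
# not code: replace the TSV to use real vectors.

.sig_vector <- function(peaks, class_bg = NULL, uniform_bg = 0.1) {
  ch <- sbs_channels()
  v <- rep(0, 96)
  names(v) <- ch$channel
  if (length(peaks)) v[names(peaks)] <- peaks
  if (!is.null(class_bg)) {
    for (cls in names(class_bg)) {
      idx <- paste0(ch$ref, ">", ch$alt) == cls
      v[idx] <- v[idx] + class_bg[[cls]] / sum(idx)
    }
  }
  v <- v + uniform_bg / 96
  v / sum(v)
}

.sig_smooth <- function(class_mult, five_mult, three_mult) {
  ch <- sbs_channels()
  w <- class_mult[paste0(ch$ref, ">", ch$alt)] *
    five_mult[ch$five] * three_mult[ch$three]
  w <- unname(w)
  names(w) <- ch$channel
  w / sum(w)
}

#' Synthetic SBS signature catalog
#'
#' Builds the packaged 96-channel catalog of ten signatures (SBS1, SBS2, SBS5,
#' SBS13, SBS17b, SBS18, SBS35, SBS40, SBS41, SBS88) as synthetic
#' approximations; see the package vignette for what they do and do not share
#' with the real COSMIC vectors. Deterministic; every column sums to 1.
#'
#' @return 96 x 10 numeric matrix, rows named by channel, columns by
#'   signature.
#' @export
sbs_catalog <- function() {
  sigs <- list(
    SBS1 = .sig_vector(
      c("A[C>T]G" = 0.21, "C[C>T]G" = 0.19, "G[C>T]G" = 0.18,
        "T[C>T]G" = 0.22),
      uniform_bg = 0.20),
    SBS2 = .sig_vector(
      c("T[C>T]A" = 0.35, "T[C>T]T" = 0.25, "T[C>T]C" = 0.16,
        "T[C>T]G" = 0.09),
      uniform_bg = 0.15),
    SBS5 = .sig_smooth(
      class_mult = c("C>A" = 0.8, "C>G" = 0.6, "C>T" = 2.2,
                     "T>A" = 0.7, "T>C" = 1.8, "T>G" = 0.6),
      five_mult = c(A = 1.2, C = 1.0, G = 0.9, T = 1.1),
      three_mult = c(A = 1.0, C = 1.1, G = 1.0, T = 1.0)),
    SBS13 = .sig_vector(
      c("T[C>G]A" = 0.28, "T[C>G]T" = 0.22, "T[C>G]C" = 0.12,
        "T[C>A]A" = 0.10, "T[C>A]T" = 0.08, "T[C>G]G" = 0.05),
      uniform_bg = 0.15),
    SBS17b = .sig_vector(
      c("C[T>G]T" = 0.35, "A[T>G]T" = 0.25, "T[T>G]T" = 0.15,
        "G[T>G]T" = 0.10),
      uniform_bg = 0.15),
    SBS18 = .sig_vector(
      c("T[C>A]T" = 0.14, "G[C>A]A" = 0.12, "T[C>A]A" = 0.10,
        "A[C>A]A" = 0.10, "C[C>A]A" = 0.08, "G[C>A]T" = 0.08),
      class_bg = list("C>A" = 0.28),
      uniform_bg = 0.10),
    SBS35 = .sig_vector(
      c("C[C>A]C" = 0.15, "C[C>A]T" = 0.12, "A[C>T]C" = 0.10,
        "C[C>T]C" = 0.10, "G[C>A]C" = 0.08),
      class_bg = list("C>T" = 0.15),
      uniform_bg = 0.30),
    SBS40 = .sig_smooth(
      class_mult = c("C>A" = 1.9, "C>G" = 0.9, "C>T" = 0.9,
                     "T>A" = 1.5, "T>C" = 0.8, "T>G" = 0.9),
      five_mult = c(A = 0.9, C = 1.1, G = 1.1, T = 0.9),
      three_mult = c(A = 1.2, C = 0.9, G = 1.0, T = 1.0)),
    SBS41 = .sig_vector(
      c("C[T>A]T" = 0.30, "A[T>A]A" = 0.20, "G[T>A]C" = 0.15),
      uniform_bg = 0.35),
    SBS88 = .sig_vector(
      c("A[T>C]T" = 0.25, "A[T>C]A" = 0.20, "A[T>A]T" = 0.15,
        "A[T>C]C" = 0.10),
      uniform_bg = 0.30)
  )
  out <- do.call(cbind, sigs)
  rownames(out) <- sbs_channels()$channel
  out
}

#' Load a signature catalog from TSV
#'
#' Expects a 96-row table whose first column holds channel names like
#' `"A[C>A]A"` and remaining columns one signature each.
#'
#' @param path TSV file; defaults to the packaged synthetic catalog.
#' @return 96 x S matrix with columns renormalized to sum to 1.
#' @export
load_signature_catalog <- function(path = system.file(
  "extdata", "signature_catalog_synthetic.tsv", package = "cryptomes")) {
  tab <- utils::read.delim(path, check.names = FALSE)
  m <- as.matrix(tab[, -1, drop = FALSE])
  rownames(m) <- tab[[1]]
  ref <- sbs_channels()$channel
  if (!setequal(rownames(m), ref)) stop("catalog must cover the 96 channels")
  m <- m[ref, , drop = FALSE]
  if (any(m < 0)) stop("catalog entries must be non-negative")
  sweep(m, 2, colSums(m), "/")
}

#' Write a signature catalog to TSV
#'
#' @param catalog 96 x S matrix (rows named by channel).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_signature_catalog <- function(catalog, path) {
  tab <- data.frame(channel = rownames(catalog), catalog,
                    check.names = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
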