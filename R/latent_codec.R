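# Encoder/decoder contract between molecules and latent vectors, plus the
# built-in codebook codec used for desk-scale work, reconstruction-rate
# validation and latent-distribution diagnostics.
#
# Molecule tables are plain data.frames with at least `id` and `smiles`
# columns; optional columns carry per-target affinities (`target`,
# `delta_g`) and the Lipinski descriptors (`mw`, `logp`, `nhd`, `nha`).
# Latent vectors are numeric vectors; sets of them are n x d matrices.

#' Validate a molecule table
#'
#' Checks the minimal schema shared by all modules: character `id` and
#' non-empty `smiles` columns, finite `delta_g` where present, and
#' non-negative integer hydrogen-bond counts where present.
#'
#' @param mols data.frame of molecule records.
#' @return the validated data.frame (invisibly unchanged).
#' @export
validate_molecules <- function(mols) {
  if (!is.data.frame(mols)) stop_data("molecule table must be a data.frame")
  for (col in c("id", "smiles")) {
    if (!col %in% names(mols)) stop_data("molecule table lacks column '", col, "'")
  }
  if (nrow(mols) > 0L) {
    if (any(!nzchar(as.character(mols$smiles)))) {
      stop_data("empty smiles string in molecule table")
    }
    if ("delta_g" %in% names(mols) && !all(is.finite(mols$delta_g))) {
      stop_data("non-finite delta_g in molecule table")
    }
    for (col in c("nhd", "nha")) {
      if (col %in% names(mols)) {
        v <- mols[[col]]
        if (any(!is.finite(v) | v < 0 | v != round(v))) {
          stop_data("'", col, "' must hold non-negative integers")
        }
      }
    }
  }
  invisible(mols)
}

#' Build a codebook codec
#'
#' A deterministic stand-in for a pretrained sequence autoencoder: each
#' molecule is paired with a fixed latent "center"; encoding looks the
#' molecule up in the codebook, decoding returns the SMILES of the nearest
#' center under Euclidean distance (ties broken by lowest codebook index).
#' `decode(encode(m))` is exact for every codebook molecule, so the codec's
#' reconstruction rate on its own codebook is 1.
#'
#' @param molecules data.frame with `id` and `smiles` columns, one row per
#'   codebook entry.
#' @param centers numeric matrix with one row per molecule (or a list of
#'   equal-length numeric vectors). Rows must be distinct.
#' @return an object of class `codebook_codec`.
#' @examples
#' mols <- data.frame(id = c("a", "b"), smiles = c("CCO", "CCN"))
#' cdc <- codebook_codec(mols, rbind(c(0, 0), c(1, 1)))
#' decode(cdc, c(0.1, -0.2))  # "CCO"
#' @export
codebook_codec <- function(molecules, centers) {
  validate_molecules(molecules)
  if (is.list(centers) && !is.matrix(centers)) {
    centers <- do.call(rbind, lapply(centers, as.numeric))
  }
  centers <- as.matrix(centers)
  storage.mode(centers) <- "double"
  if (nrow(molecules) < 1L) stop_config("empty codebook")
  if (nrow(centers) != nrow(molecules)) {
    stop_config("codebook size mismatch: ", nrow(molecules), " molecules vs ",
                nrow(centers), " centers")
  }
  if (!all(is.finite(centers))) stop_config("non-finite codebook center")
  if (anyDuplicated(centers) > 0L) stop_config("duplicate codebook centers")
  structure(
    list(ids = as.character(molecules$id),
         smiles = as.character(molecules$smiles),
         centers = unname(centers),
         dimension = ncol(centers)),
    class = "codebook_codec")
}

#' @export
print.codebook_codec <- function(x, ...) {
  cat("Codebook codec:", length(x$ids), "molecules, latent dimension",
      x$dimension, "\n")
  invisible(x)
}

#' Encode molecules into latent space
#'
#' @param codec a codec object (e.g. from [codebook_codec()]).
#' @param molecules data.frame of molecule records, or a character vector of
#'   molecule ids.
#' @param ... passed to methods.
#' @return numeric matrix, one latent row per molecule.
#' @export
encode <- function(codec, molecules, ...) UseMethod("encode")

#' @export
encode.codebook_codec <- function(codec, molecules, ...) {
  ids <- if (is.character(molecules)) molecules else as.character(molecules$id)
  idx <- match(ids, codec$ids)
  if (anyNA(idx)) {
    stop_domain("molecule(s) not in codebook: ",
                paste(head(ids[is.na(idx)], 3L), collapse = ", "))
  }
  codec$centers[idx, , drop = FALSE]
}

#' Decode latent vectors back to SMILES strings
#'
#' @param codec a codec object.
#' @param z numeric latent vector, or matrix with one vector per row.
#' @param ... passed to methods.
#' @return character vector of SMILES strings, one per input vector.
#' @export
decode <- function(codec, z, ...) UseMethod("decode")

#' @export
decode.codebook_codec <- function(codec, z, ...) {
  if (!is.matrix(z)) z <- matrix(check_latent(z, "z"), nrow = 1L)
  if (ncol(z) != codec$dimension) {
    stop_domain("latent dimension ", ncol(z), " does not match codec dimension ",
                codec$dimension)
  }
  # squared distances via ||z||^2 - 2 z.c + ||c||^2; the ||z||^2 term is
  # constant per query and dropped. which.min takes the lowest index on ties.
  cross <- z %*% t(codec$centers)
  cnorm <- rowSums(codec$centers^2)
  nearest <- apply(-2 * cross + rep(cnorm, each = nrow(z)), 1L, which.min)
  codec$smiles[nearest]
}

#' Encode-decode reconstruction rate
#'
#' Fraction of molecules whose encode-then-decode round trip returns the
#' original SMILES string. Comparison is on raw strings unless a
#' `canonicalize` function is supplied, in which case both sides are passed
#' through it first (useful with a cheminformatics canonicalizer when
#' SMILES may have multiple spellings).
#'
#' @param codec a codec object.
#' @param molecules non-empty molecule data.frame.
#' @param canonicalize optional function mapping a character vector of
#'   SMILES to canonical forms.
#' @return reconstruction rate in `[0, 1]`.
#' @export
reconstruction_rate <- function(codec, molecules, canonicalize = NULL) {
  validate_molecules(molecules)
  if (nrow(molecules) == 0L) stop_domain("empty molecule list")
  out <- decode(codec, encode(codec, molecules))
  orig <- as.character(molecules$smiles)
  if (!is.null(canonicalize)) {
    out <- canonicalize(out)
    orig <- canonicalize(orig)
  }
  mean(out == orig)
}

#' Per-index latent profile
#'
#' Summarizes a set of latent vectors by one non-negative value per latent
#' index. The default (`"abs_mean"`) is the absolute value of the per-index
#' mean, which reveals sign cancellation across a dataset; `"mean_abs"`
#' averages absolute values instead.
#'
#' @param vectors numeric matrix of latent vectors (rows) or list of
#'   equal-length numeric vectors.
#' @param method `"abs_mean"` (default) or `"mean_abs"`.
#' @return numeric vector of length d, entries >= 0.
#' @export
latent_profile <- function(vectors, method = c("abs_mean", "mean_abs")) {
  method <- match.arg(method)
  if (is.list(vectors) && !is.matrix(vectors)) {
    d <- unique(lengths(vectors))
    if (length(vectors) == 0L) stop_domain("empty vector list")
    if (length(d) != 1L) stop_domain("ragged latent dimensions")
    vectors <- do.call(rbind, lapply(vectors, as.numeric))
  }
  vectors <- as.matrix(vectors)
  if (nrow(vectors) == 0L) stop_domain("empty vector list")
  if (!all(is.finite(vectors))) stop_domain("non-finite latent entries")
  if (method == "abs_mean") abs(colMeans(vectors)) else colMeans(abs(vectors))
}

#' Divergence between two latent profiles
#'
#' Mean absolute per-index difference; zero iff the profiles are identical.
#' Used as the diagnostic that generated latent vectors keep the
#' distribution pattern the decoder was trained on.
#'
#' @param p,q equal-length numeric profiles (from [latent_profile()]).
#' @return non-negative scalar.
#' @export
profile_divergence <- function(p, q) {
  p <- check_latent(p, "p")
  q <- check_latent(q, "q")
  if (length(p) != length(q)) {
    stop_domain("profile dimensions differ: ", length(p), " vs ", length(q))
  }
  mean(abs(p - q))
}
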