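# Exact (non-neural) semantic-pointer algebra: the holographic reduced
# representation operations that the neural circuits approximate, used as
# the reference oracle throughout.

#' Random unit semantic pointer
#'
#' Draws a vector uniformly from the unit sphere in `D` dimensions.
#'
#' @param D Dimensionality.
#' @param seed Optional integer seed.
#' @return Unit-length numeric vector.
#' @export
random_pointer <- function(D, seed = NULL) {
  D <- assert_count(D, "D")
  with_seed(seed, {
    v <- stats::rnorm(D)
    v / sqrt(sum(v^2))
  })
}

#' Circular convolution (binding)
#'
#' The binding operation of holographic reduced representations:
#' \deqn{u_i = \sum_j v_j w_{(i - j) \bmod D}} (0-based circular indexing, so
#' the first standard basis vector is the identity element).  The transform
#' path computes the element-wise product in Fourier space in
#' \eqn{O(D \log D)}; the direct path evaluates the sum in \eqn{O(D^2)}.
#'
#' @param v,w Equal-length numeric vectors.
#' @param method `"fft"` (default) or `"direct"`.
#' @return The bound vector `v` \eqn{\circledast} `w`.
#' @examples
#' circular_convolution(c(1, 2, 3), c(0, 1, 0))  # (3, 1, 2)
#' @export
circular_convolution <- function(v, w, method = c("fft", "direct")) {
  method <- match.arg(method)
  if (length(v) != length(w)) {
    stop("`v` and `w` must have the same dimensionality", call. = FALSE)
  }
  D <- length(v)
  if (method == "fft") {
    Re(stats::fft(stats::fft(v) * stats::fft(w), inverse = TRUE)) / D
  } else {
    u <- numeric(D)
    for (i in seq_len(D)) {
      idx <- ((i - 1) - seq(0, D - 1)) %% D + 1
      u[i] <- sum(v * w[idx])
    }
    u
  }
}

#' Involution (approximate inverse for binding)
#'
#' Index reversal \eqn{w^{-1} = (w_1, w_D, w_{D-1}, \dots, w_2)}; applying it
#' twice returns the original vector.
#'
#' @param w Numeric vector.
#' @return The involuted vector.
#' @export
involution <- function(w) {
  D <- length(w)
  if (D <= 1) {
    return(w)
  }
  c(w[1], rev(w[-1]))
}

#' Unbind a semantic pointer
#'
#' Recovers an operand from a bound pair by convolving with the involution
#' of the other operand, \eqn{v \approx u \circledast w^{-1}}.  For a
#' unitary `w` the recovery is exact.
#'
#' @param u Bound vector.
#' @param w The operand to unbind.
#' @return The (approximately) recovered operand.
#' @export
unbind <- function(u, w) {
  if (length(u) != length(w)) {
    stop("`u` and `w` must have the same dimensionality", call. = FALSE)
  }
  circular_convolution(u, involution(w))
}

#' Random unitary semantic pointer
#'
#' Generates a vector whose discrete-Fourier coefficients all have magnitude
#' 1: binding with it preserves the length of the other operand, and
#' unbinding inverts binding exactly.  Random phases are drawn for the free
#' Fourier bins with conjugate symmetry so the result is real; the vector has
#' unit norm by Parseval's identity.
#'
#' @param D Dimensionality.
#' @param seed Optional integer seed.
#' @return Unit-length unitary vector.
#' @export
make_unitary <- function(D, seed = NULL) {
  D <- assert_count(D, "D")
  with_seed(seed, {
    coeffs <- complex(D)
    coeffs[1] <- sample(c(-1, 1), 1)
    K <- (D - 1) %/% 2
    if (K >= 1) {
      phases <- stats::runif(K, 0, 2 * pi)
      coeffs[1 + seq_len(K)] <- exp(1i * phases)
      coeffs[D + 1 - seq_len(K)] <- Conj(coeffs[1 + seq_len(K)])
    }
    if (D %% 2 == 0) {
      coeffs[D / 2 + 1] <- sample(c(-1, 1), 1)
    }
    Re(stats::fft(coeffs, inverse = TRUE)) / D
  })
}

#' Is a vector unitary?
#'
#' @param w Numeric vector.
#' @param tol Tolerance on the Fourier-coefficient magnitudes.
#' @return `TRUE` if all Fourier coefficients of `w` have magnitude 1.
#' @export
is_unitary <- function(w, tol = 1e-8) {
  all(abs(Mod(stats::fft(w)) - 1) < tol)
}

#' Dot-product similarity
#'
#' \eqn{\sum_i v_i w_i}; lies in `[-1, 1]` for unit vectors.
#'
#' @param v,w Equal-length numeric vectors.
#' @return Scalar similarity.
#' @export
dot_similarity <- function(v, w) {
  if (length(v) != length(w)) {
    stop("`v` and `w` must have the same dimensionality", call. = FALSE)
  }
  sum(v * w)
}

#' Read and write pointer vocabularies
#'
#' A vocabulary is a named set of equal-dimensional pointers, stored as a
#' matrix with one row per pointer.  The CSV layout is one row per pointer:
#' name followed by the `D` components; JSON stores a name -> components map.
#'
#' @param vocab Named list or row-named matrix of pointers.
#' @param path File path (`.csv` or `.json`).
#' @return `read_vocabulary` returns a row-named matrix.
#' @export
write_vocabulary <- function(vocab, path) {
  if (is.list(vocab)) {
    vocab <- do.call(rbind, vocab)
  }
  vocab <- as.matrix(vocab)
  if (is.null(rownames(vocab))) {
    stop("vocabulary pointers must be named", call. = FALSE)
  }
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(
      stats::setNames(
        lapply(seq_len(nrow(vocab)), function(i) unname(vocab[i, ])),
        rownames(vocab)
      ),
      path,
      digits = NA, auto_unbox = FALSE
    )
  } else {
    df <- data.frame(name = rownames(vocab), vocab, row.names = NULL)
    utils::write.csv(df, path, row.names = FALSE)
  }
  invisible(path)
}

#' @rdname write_vocabulary
#' @export
read_vocabulary <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    lst <- jsonlite::read_json(path, simplifyVector = TRUE)
    mat <- do.call(rbind, lst)
  } else {
    df <- utils::read.csv(path, check.names = FALSE)
    mat <- as.matrix(df[, -1, drop = FALSE])
    rownames(mat) <- df[[1]]
  }
  storage.mode(mat) <- "double"
  colnames(mat) <- NULL
  mat
}
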