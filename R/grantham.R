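#' Grantham amino-acid properties and distance matrix
#'
#' Grantham's physicochemical distance between residues i and j is
#' \deqn{D_{ij} = \rho \left[ \alpha (c_i - c_j)^2 + \beta (p_i - p_j)^2 +
#'   \gamma (v_i - v_j)^2 \right]^{1/2}}
#' with composition `c` (atomic weight ratio of non-carbon side-chain
#' elements), polarity `p` and molecular volume `v`, weights
#' \eqn{\alpha = 1.833}, \eqn{\beta = 0.1018}, \eqn{\gamma = 0.000399}, and
#' \eqn{\rho = 50.723} scaling the mean inter-residue distance to 100.
#' Distances above 50 are conventionally treated as radical substitutions.
#'
#' @return `grantham_properties()`: data.frame of the published per-residue
#'   `c`, `p`, `v` values. `grantham_matrix()`: symmetric 20x20 integer
#'   matrix (zero diagonal) of distances rounded to the nearest integer.
#' @export
grantham_properties <- function() {
  data.frame(
    residue = c("S", "R", "L", "P", "T", "A", "V", "G", "I", "F",
                "Y", "C", "H", "Q", "N", "K", "D", "E", "M", "W"),
    c = c(1.42, 0.65, 0, 0.39, 0.71, 0, 0, 0.74, 0, 0,
          0.20, 2.75, 0.58, 0.89, 1.33, 0.33, 1.38, 0.92, 0, 0.13),
    p = c(9.2, 10.5, 4.9, 8.0, 8.6, 8.1, 5.9, 9.0, 5.2, 5.2,
          6.2, 5.5, 10.4, 10.5, 11.6, 11.3, 13.0, 12.3, 5.7, 5.4),
    v = c(32, 124, 111, 32.5, 61, 31, 84, 3, 111, 132,
          136, 55, 96, 85, 56, 119, 54, 83, 105, 170),
    stringsAsFactors = FALSE
  )
}

grantham_env <- new.env(parent = emptyenv())

#' @rdname grantham_properties
#' @export
grantham_matrix <- function() {
  if (!is.null(grantham_env$matrix)) {
    return(grantham_env$matrix)
  }
  props <- grantham_properties()
  alpha <- 1.833; beta <- 0.1018; gamma <- 0.000399; rho <- 50.723
  n <- nrow(props)
  d <- matrix(0L, n, n, dimnames = list(props$residue, props$residue))
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      raw <- rho * sqrt(alpha * (props$c[i] - props$c[j])^2 +
                        beta  * (props$p[i] - props$p[j])^2 +
                        gamma * (props$v[i] - props$v[j])^2)
      d[i, j] <- d[j, i] <- as.integer(round(raw))
    }
  }
  grantham_env$matrix <- d
  d
}

#' Grantham distance between two residues
#'
#' @param aa1,aa2 One-letter codes among the 20 standard amino acids.
#' @return Non-negative integer distance; 0 iff `aa1 == aa2`.
#' @examples
#' grantham_distance("A", "T")  # 58
#' grantham_distance("Y", "H")  # 83
#' @export
grantham_distance <- function(aa1, aa2) {
  m <- grantham_matrix()
  ok <- c(aa1, aa2) %in% rownames(m)
  if (!all(ok)) {
    stop("not a standard amino acid: ",
         paste(unique(c(aa1, aa2)[!ok]), collapse = ", "), call. = FALSE)
  }
  m[aa1, aa2]
}
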