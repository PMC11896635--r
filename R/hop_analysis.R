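#' Spin-diabatic character weights of a surface hop
#'
#' For a hop between two spin-adiabatic states, attributes the event to
#' pairs of spin-diabatic states by the product of squared expansion
#' coefficients: \eqn{w_{ij} = |U_{i,\mathrm{from}}|^2 |U_{j,\mathrm{to}}|^2},
#' with the three components of each triplet summed into the parent triplet.
#' By unitarity of the columns the weights of each hop sum to exactly 1.
#'
#' @param U Unitary matrix at the hop (spin-diabatic x spin-adiabatic).
#' @param from,to Spin-adiabatic indices (1-based). Equal indices are only
#'   permitted with `diagnostic = TRUE` (diagonal "hops" are an artifact of
#'   counting character transfer only at hop events).
#' @param n_singlets,n_triplets Scalar-state counts defining the merge.
#' @param diagnostic Allow `from == to`.
#' @return `(n_singlets + n_triplets)^2` non-negative matrix of class
#'   `hop_character`, rows = initial scalar state, cols = final; dimnames
#'   are the scalar labels.
#' @export
hop_character_weights <- function(U, from, to, n_singlets, n_triplets,
                                  diagnostic = FALSE) {
  d <- n_singlets + 3L * n_triplets
  if (nrow(U) != d) stop("U dimension does not match state counts")
  if (from < 1L || from > d || to < 1L || to > d) stop("invalid state indices")
  if (from == to && !diagnostic)
    stop("from == to only permitted in diagnostic mode")
  wi <- Mod(U[, from])^2
  wj <- Mod(U[, to])^2
  comp_of <- c(seq_len(n_singlets),
               if (n_triplets > 0L) n_singlets + rep(seq_len(n_triplets), each = 3L))
  mi <- as.vector(tapply(wi, comp_of, sum))
  mj <- as.vector(tapply(wj, comp_of, sum))
  W <- outer(mi, mj)
  labs <- c(paste0("S", seq_len(n_singlets) - 1L),
            if (n_triplets > 0L) paste0("T", seq_len(n_triplets)))
  dimnames(W) <- list(from = labs, to = labs)
  structure(W, class = c("hop_character", class(W)))
}

#' Aggregate hop-character weights over an ensemble
#'
#' Sums the per-hop character matrices of all accepted hops (optionally
#' including frustrated ones) across trajectories. The total equals the
#' number of hops counted.
#'
#' @param trajectories List of `trajectory` objects.
#' @param include_frustrated Also count rejected hops. Default FALSE.
#' @return Summed weight matrix (scalar-state by scalar-state) with
#'   attribute `n_hops`.
#' @export
aggregate_hop_characters <- function(trajectories, include_frustrated = FALSE) {
  stopifnot(length(trajectories) > 0L)
  tr1 <- trajectories[[1]]
  nS <- sum(startsWith(tr1$state_labels, "S"))
  nT <- sum(startsWith(tr1$state_labels, "T"))
  n <- nS + nT
  W <- matrix(0, n, n, dimnames = list(from = tr1$state_labels, to = tr1$state_labels))
  n_hops <- 0L
  for (tr in trajectories) {
    h <- tr$hops
    if (!include_frustrated) h <- h[h$accepted, , drop = FALSE]
    for (r in seq_len(nrow(h))) {
      W <- W + hop_character_weights(h$U[[r]], h$from[r], h$to[r], nS, nT)
      n_hops <- n_hops + 1L
    }
  }
  attr(W, "n_hops") <- n_hops
  W
}

#' Dihedral angle of four points
#'
#' Standard dihedral from the two plane normals of (p1, p2, p3) and
#' (p2, p3, p4), reported in \[0, 360) with the trans-planar arrangement at
#' 180 degrees and cis-planar at 0.
#'
#' @param p1,p2,p3,p4 Numeric 3-vectors (any consistent length unit).
#' @return Angle in degrees in \[0, 360).
#' @examples
#' dihedral_angle(c(1, 0, 0), c(0, 0, 0), c(0, 1, 0), c(-1, 1, 0))  # 180
#' @export
dihedral_angle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- cross3(b1, b2); n2 <- cross3(b2, b3)
  if (sqrt(sum(n1^2)) < 1e-12 || sqrt(sum(n2^2)) < 1e-12)
    stop("collinear points: dihedral undefined")
  m1 <- cross3(n1, b2 / sqrt(sum(b2^2)))
  x <- sum(n1 * n2); y <- sum(m1 * n2)
  ang <- atan2(y, x) * 180 / pi          # signed (-180, 180], cis = 0
  (ang + 360) %% 360
}

#' Read an XYZ geometry file
#'
#' Standard XYZ: an atom count line, a comment line, then one
#' `element x y z` line per atom (angstroms); multiple frames may be
#' concatenated. Useful for feeding geometries to [dihedral_angle()].
#'
#' @param path Path to an `.xyz` file.
#' @return A tibble with `frame`, `atom` (index within frame), `element`,
#'   `x`, `y`, `z`.
#' @export
read_xyz <- function(path) {
  lines <- readLines(path)
  out <- list()
  i <- 1L; frame <- 0L
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1L; next }
    n <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(n) || n < 1L) stop("malformed XYZ: expected atom count at line ", i)
    if (i + 1L + n > length(lines)) stop("malformed XYZ: truncated frame at line ", i)
    frame <- frame + 1L
    body <- lines[(i + 2L):(i + 1L + n)]
    parts <- strsplit(trimws(body), "\\s+")
    out[[frame]] <- tibble::tibble(
      frame = frame,
      atom = seq_len(n),
      element = vapply(parts, `[[`, "", 1L),
      x = as.numeric(vapply(parts, `[[`, "", 2L)),
      y = as.numeric(vapply(parts, `[[`, "", 3L)),
      z = as.numeric(vapply(parts, `[[`, "", 4L))
    )
    i <- i + 2L + n
  }
  if (frame == 0L) stop("no frames in XYZ file")
  dplyr::bind_rows(out)
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Occurrence histogram of an angular coordinate
#'
#' Bins values (degrees) with a fixed bin width, optionally accumulating
#' per-value weights (e.g. hop-character weights) instead of counts. The
#' total of the counts equals the number of inputs (or the sum of weights)
#' exactly.
#'
#' @param values Numeric vector of angles (degrees), non-empty.
#' @param bin_width_deg Bin width in degrees, > 0. Default 1.
#' @param weights Optional non-negative per-value weights.
#' @param label Free-text label stored on the result.
#' @return Tibble of class `angle_histogram` with `bin_left`, `bin_right`,
#'   `bin_mid` (degrees) and `count`.
#' @export
occurrence_histogram <- function(values, bin_width_deg = 1, weights = NULL,
                                 label = "") {
  if (length(values) == 0L) stop("empty input")
  if (bin_width_deg <= 0) stop("bin_width_deg must be > 0")
  if (is.null(weights)) weights <- rep(1, length(values))
  if (length(weights) != length(values)) stop("weights length mismatch")
  lo <- floor(min(values) / bin_width_deg) * bin_width_deg
  hi <- ceiling(max(values) / bin_width_deg + 1e-12) * bin_width_deg
  if (hi <= lo) hi <- lo + bin_width_deg
  edges <- seq(lo, hi, by = bin_width_deg)
  idx <- pmin(findInterval(values, edges, rightmost.closed = TRUE),
              length(edges) - 1L)
  counts <- vapply(seq_len(length(edges) - 1L),
                   function(b) sum(weights[idx == b]), numeric(1))
  out <- tibble::tibble(bin_left = edges[-length(edges)], bin_right = edges[-1],
                        bin_mid = (edges[-length(edges)] + edges[-1]) / 2,
                        count = counts)
  structure(out, label = label, bin_width_deg = bin_width_deg,
            class = c("angle_histogram", class(out)))
}
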