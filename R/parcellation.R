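#' Construct a parcellation table
#'
#' A parcellation is a data frame with one row per brain region (node) and
#' columns `name` (region label, identical across hemispheres for homotopic
#' partners), `hemi` (`"L"` or `"R"`), MNI-style coordinates `x`, `y`, `z` in
#' millimetres, and optionally `network` (e.g. one of the seven canonical
#' resting-state networks). Node ids are the row indices `1..N`.
#'
#' @param df data frame with at least columns `name`, `hemi`, `x`, `y`, `z`;
#'   optionally `network`.
#' @return The validated data frame with class `"parcellation"` prepended.
#' @examples
#' as_parcellation(data.frame(name = c("a", "a"), hemi = c("L", "R"),
#'                            x = c(-10, 10), y = 0, z = 0))
#' @export
as_parcellation <- function(df) {
  stopifnot(is.data.frame(df))
  need <- c("name", "hemi", "x", "y", "z")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stop("parcellation is missing columns: ", paste(missing_cols, collapse = ", "))
  df$name <- as.character(df$name)
  df$hemi <- toupper(substr(as.character(df$hemi), 1L, 1L))
  if (!all(df$hemi %in% c("L", "R")))
    stop("hemisphere labels must start with 'L'/'l' or 'R'/'r'")
  co <- as.matrix(df[, c("x", "y", "z")])
  if (!all(is.finite(co)))
    stop("non-finite coordinates in parcellation")
  if (!is.null(df$network)) df$network <- as.character(df$network)
  class(df) <- unique(c("parcellation", class(df)))
  df
}

#' Coordinates of a parcellation as an N x 3 matrix
#' @param parc a [as_parcellation()] table.
#' @return numeric matrix with columns x, y, z.
#' @export
parc_coords <- function(parc) {
  as.matrix(as.data.frame(parc)[, c("x", "y", "z")])
}

#' Pairwise Euclidean distances between region centroids
#'
#' Distances (in mm) between node coordinates, used both by the exponential
#' distance rule and by the spatial weighting of the local Kuramoto order
#' parameter.
#'
#' @param parc a parcellation table, or an N x 3 coordinate matrix.
#' @return symmetric N x N matrix of distances with zero diagonal.
#' @examples
#' p <- as_parcellation(data.frame(name = c("a", "a"), hemi = c("L", "R"),
#'                                 x = c(0, 3), y = c(0, 4), z = 0))
#' euclidean_distances(p)[1, 2] # 5
#' @export
euclidean_distances <- function(parc) {
  co <- if (inherits(parc, "parcellation")) parc_coords(parc) else as.matrix(parc)
  if (nrow(co) < 2L) stop("need at least 2 nodes")
  if (!all(is.finite(co))) stop("non-finite coordinates")
  d <- as.matrix(stats::dist(co))
  dimnames(d) <- NULL
  d
}

#' Homotopic (mirror) node pairs of a bilateral parcellation
#'
#' Pairs left/right regions by identical region name across hemispheres.
#' Names carrying a `lh.`/`rh.` (or `lh_`/`rh_`) hemisphere prefix are
#' matched after stripping the prefix.
#'
#' @param parc a parcellation table.
#' @return integer matrix with columns `left`, `right`, one row per pair
#'   (N/2 rows).
#' @export
homotopic_pairs <- function(parc) {
  parc <- as_parcellation(as.data.frame(parc))
  n <- nrow(parc)
  if (n %% 2L != 0L) stop("odd number of nodes: cannot pair hemispheres")
  base <- sub("^[lr]h[._]", "", parc$name, ignore.case = TRUE)
  left <- which(parc$hemi == "L")
  right <- which(parc$hemi == "R")
  if (length(left) != length(right))
    stop("unequal hemisphere sizes: ", length(left), " left vs ",
         length(right), " right")
  idx <- match(base[left], base[right])
  bad <- base[left][is.na(idx)]
  dup <- base[left][duplicated(base[left])]
  if (length(bad) || length(dup))
    stop("unpaired or duplicated region names: ",
         paste(unique(c(bad, dup)), collapse = ", "))
  cbind(left = left, right = right[idx])
}
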