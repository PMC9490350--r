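#' Area-level geography container
#'
#' Bundles everything the spatial models need to know about the study region:
#' ordered area identifiers, planar centroid coordinates, populations and a
#' binary contiguity (adjacency) matrix. Centroids feed the distance-based
#' spline surface, populations feed the incidence offset
#' \eqn{\log(\xi_i) = \log(\mathrm{population}_i / 10^5)} and the gravity
#' model, and the adjacency matrix feeds the CAR/BYM2 comparator.
#'
#' @param area_ids character or integer vector of unique area identifiers.
#' @param centroids numeric n x 2 matrix of planar coordinates (projected
#'   units); duplicate rows are rejected because the thin-plate radial basis
#'   needs distinct knots.
#' @param populations numeric vector of strictly positive population counts.
#' @param adjacency binary symmetric n x n matrix with zero diagonal, or
#'   `NULL` if no contiguity structure is available.
#' @return An object of class `sm_geography`.
#' @export
geography <- function(area_ids, centroids, populations, adjacency = NULL) {
  centroids <- as.matrix(centroids)
  n <- length(area_ids)
  if (anyDuplicated(area_ids)) stop("area_ids must be unique")
  if (nrow(centroids) != n || ncol(centroids) != 2L)
    stop("centroids must be an n x 2 matrix matching area_ids")
  if (!is.numeric(populations) || length(populations) != n)
    stop("populations must be a numeric vector of length n")
  if (any(!is.finite(populations)) || any(populations <= 0))
    stop("populations must be strictly positive and finite")
  if (anyDuplicated(centroids) > 0L)
    stop("duplicate centroid rows are not allowed")
  if (!is.null(adjacency)) {
    adjacency <- as.matrix(adjacency)
    check_adjacency(adjacency, n)
  }
  structure(
    list(area_ids = area_ids,
         centroids = unname(centroids),
         populations = as.numeric(populations),
         adjacency = if (is.null(adjacency)) NULL else unname(adjacency)),
    class = "sm_geography")
}

check_adjacency <- function(W, n = nrow(W)) {
  if (nrow(W) != n || ncol(W) != n) stop("adjacency must be n x n")
  if (!all(W %in% c(0, 1))) stop("adjacency must be binary (0/1)")
  if (any(diag(W) != 0)) stop("adjacency must have a zero diagonal")
  if (!isTRUE(all.equal(W, t(W)))) stop("adjacency must be symmetric")
  invisible(W)
}

#' @export
print.sm_geography <- function(x, ...) {
  cat(sprintf("<sm_geography> %d areas; populations %.0f-%.0f; %s adjacency\n",
              length(x$area_ids), min(x$populations), max(x$populations),
              if (is.null(x$adjacency)) "no" else
                sprintf("%d-edge", sum(x$adjacency) / 2)))
  invisible(x)
}

#' Read a centroid table
#'
#' Expects columns `area_id`, `x`, `y`; rows are returned in file order.
#'
#' @param path CSV file path.
#' @return list with `area_ids` and an n x 2 `centroids` matrix.
#' @export
read_centroids_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("area_id", "x", "y")
  if (!all(need %in% names(d)))
    stop("centroid CSV must have columns area_id, x, y")
  list(area_ids = d$area_id, centroids = cbind(d$x, d$y))
}

#' Read an area data table
#'
#' Columns `area_id`, `count`, `population` and optionally `trials`
#' (binomial models).
#'
#' @param path CSV file path.
#' @return data.frame in file order.
#' @export
read_area_data_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("area_id", "count", "population")
  if (!all(need %in% names(d)))
    stop("area data CSV must have columns area_id, count, population")
  d
}

#' Read a dense symmetric flow matrix
#'
#' Dense CSV with a header row and a leading id column; row and column ids
#' must match and the matrix must be square. Mild asymmetries are
#' symmetrized as (M + t(M))/2 with a warning, mirroring the assumption that
#' outgoing and returning travellers balance.
#'
#' @param path CSV file path.
#' @param area_ids optional ids to check/reorder against.
#' @return symmetric numeric matrix with zero diagonal.
#' @export
read_flow_csv <- function(path, area_ids = NULL) {
  d <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  ids <- as.character(d[[1L]])
  M <- as.matrix(d[, -1L, drop = FALSE])
  if (nrow(M) != ncol(M)) stop("flow matrix must be square")
  if (!identical(ids, colnames(M)))
    stop("flow matrix row ids must equal column ids")
  if (!is.null(area_ids)) {
    area_ids <- as.character(area_ids)
    if (!setequal(ids, area_ids))
      stop("flow matrix ids do not match the geography")
    M <- M[match(area_ids, ids), match(area_ids, ids)]
  }
  storage.mode(M) <- "double"
  flow_matrix(M)
}

#' Read an adjacency edge list
#'
#' Header `i,j`; 0-based indices into the sorted `area_id` order (stated
#' explicitly to avoid off-by-one ambiguity).
#'
#' @param path CSV file path.
#' @param n number of areas.
#' @return binary symmetric n x n matrix.
#' @export
read_edge_list_csv <- function(path, n) {
  d <- utils::read.csv(path)
  if (!all(c("i", "j") %in% names(d))) stop("edge list must have columns i, j")
  if (any(d$i < 0 | d$i >= n | d$j < 0 | d$j >= n))
    stop("edge indices out of range (0-based)")
  W <- matrix(0, n, n)
  W[cbind(d$i + 1L, d$j + 1L)] <- 1
  W <- pmax(W, t(W))
  diag(W) <- 0
  W
}

#' Write a flow matrix as dense CSV
#' @param flows symmetric flow matrix.
#' @param area_ids ids for the header row/column.
#' @param path output path.
#' @export
write_flow_csv <- function(flows, area_ids, path) {
  d <- data.frame(area_id = area_ids, flows, check.names = FALSE)
  names(d) <- c("area_id", as.character(area_ids))
  utils::write.csv(d, path, row.names = FALSE)
  invisible(path)
}
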