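# Internal helpers shared across modules.
#
# Coordinate convention (used everywhere): images are matrices indexed
# [row, col] with row = axial/depth (y) and col = lateral (x).  Pixel centers
# sit on an integer grid; physical position of pixel (i, j) is
# ((j - 1) * pixel_size_mm, (i - 1) * pixel_size_mm) as (x, y) in mm.

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores the global RNG state so generators are pure functions
#' of their (spec, seed) arguments and never disturb the caller's stream.
#'
#' @param seed integer seed, or `NULL` to use the current stream.
#' @param expr expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single integer", call. = FALSE)
  }
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  expr
}

# shift a matrix so that out[r, c] = m[r + dr, c + dc], zero-filled outside
shift_mat <- function(m, dr, dc, fill = 0) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(fill, nr, nc)
  rs <- max(1L, 1L + dr):min(nr, nr + dr)
  cs <- max(1L, 1L + dc):min(nc, nc + dc)
  if (length(rs) < 1L || length(cs) < 1L) return(out)
  out[rs - dr, cs - dc] <- m[rs, cs]
  out
}

# 8-neighbor count of TRUE pixels for a logical matrix
neighbor_count8 <- function(m) {
  m <- m * 1
  shift_mat(m, -1, 0) + shift_mat(m, 1, 0) + shift_mat(m, 0, -1) +
    shift_mat(m, 0, 1) + shift_mat(m, -1, -1) + shift_mat(m, -1, 1) +
    shift_mat(m, 1, -1) + shift_mat(m, 1, 1)
}

#' Label 8-connected foreground components
#'
#' EBImage's `bwlabel()` uses 4-connectivity; vessel maps use the standard
#' 8-connected-foreground / 4-connected-background duality, so this labels
#' with 8-connectivity via the pixel adjacency graph.
#'
#' @param mask logical matrix.
#' @return integer matrix of component labels (0 = background).
#' @keywords internal
label8 <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  idx <- which(mask)
  lab <- matrix(0L, nr, nc)
  n <- length(idx)
  if (n == 0L) return(lab)
  id <- integer(nr * nc)
  id[idx] <- seq_len(n)
  r <- (idx - 1L) %% nr + 1L
  co <- (idx - 1L) %/% nr + 1L
  edges <- vector("list", 4L)
  shifts <- list(c(1L, 0L), c(0L, 1L), c(1L, 1L), c(-1L, 1L))
  for (k in seq_along(shifts)) {
    dr <- shifts[[k]][1L]; dc <- shifts[[k]][2L]
    ok <- r + dr >= 1L & r + dr <= nr & co + dc >= 1L & co + dc <= nc
    nb <- idx[ok] + dr + dc * nr
    keep <- mask[nb]
    edges[[k]] <- cbind(id[idx[ok][keep]], id[nb[keep]])
  }
  el <- do.call(rbind, edges)
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  if (!is.null(el) && nrow(el) > 0L) g <- igraph::add_edges(g, t(el))
  memb <- igraph::components(g)$membership
  lab[idx] <- as.integer(memb)
  lab
}

# polyline arc length for an n x 2 coordinate matrix
polyline_length <- function(p) {
  if (nrow(p) < 2L) return(0)
  d <- diff(p)
  sum(sqrt(rowSums(d^2)))
}

stopifnot_scalar_pos <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x <= 0) {
    stop(sprintf("`%s` must be a single positive number", name), call. = FALSE)
  }
  invisible(x)
}

as_matrix <- function(x) {
  if (inherits(x, "Image")) x <- EBImage::imageData(x)
  m <- as.matrix(x)
  dimnames(m) <- NULL
  m
}
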