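#' Pearson correlation of two feature vectors
#'
#' Textbook product-moment correlation: covariance over the product of
#' sample standard deviations. Used for interregional edges, where the
#' observations are a region's k standardized morphometric features.
#'
#' @param u,v numeric vectors of equal length >= 2.
#' @param names optional c(name_u, name_v) for error messages.
#' @return Correlation in `[-1, 1]`.
#' @export
pearson_cor <- function(u, v, names = c("u", "v")) {
  stopifnot(length(u) == length(v), length(u) >= 2L)
  du <- u - mean(u)
  dv <- v - mean(v)
  su <- sqrt(sum(du^2))
  sv <- sqrt(sum(dv^2))
  if (su == 0 || sv == 0) {
    zero <- names[c(su == 0, sv == 0)]
    stop("zero-variance feature vector: correlation undefined for region(s) ",
         paste(zero, collapse = ", "))
  }
  r <- sum(du * dv) / (su * sv)
  max(-1, min(1, r))
}

#' Build one subject's morphological brain network
#'
#' Each region's five standardized features form a feature vector; the
#' network edge between two regions is the Pearson correlation of their
#' vectors. For 68 regions this yields a symmetric matrix with 2278 unique
#' weighted edges; the diagonal is fixed to 0 (self-connections excluded).
#'
#' @param tensor a standardized [feature_tensor()].
#' @param subject subject identifier or index.
#' @return An object of class `conn_matrix`: list with `r` (68 x 68 signed
#'   correlation matrix), `subject`, `regions`.
#' @export
build_network <- function(tensor, subject) {
  stopifnot(inherits(tensor, "feature_tensor"))
  if (!tensor$standardized) {
    stop("tensor must be z-scored before network construction ",
         "(see zscore_features)")
  }
  if (is.character(subject)) {
    s <- match(subject, tensor$subjects)
    if (is.na(s)) stop("unknown subject: ", subject)
  } else {
    s <- as.integer(subject)
  }
  x <- tensor$values[s, , , drop = FALSE]
  dim(x) <- dim(tensor$values)[2:3]          # regions x features
  # row-standardize and take cross products: vectorized pairwise Pearson
  cx <- x - rowMeans(x)
  norms <- sqrt(rowSums(cx^2))
  if (any(norms == 0)) {
    stop("zero-variance feature vector: correlation undefined for region(s) ",
         paste(tensor$regions[norms == 0], collapse = ", "))
  }
  cx <- cx / norms
  r <- tcrossprod(cx)
  r[r > 1] <- 1
  r[r < -1] <- -1
  diag(r) <- 0
  dimnames(r) <- list(tensor$regions, tensor$regions)
  structure(list(r = r, subject = tensor$subjects[s],
                 regions = tensor$regions),
            class = "conn_matrix")
}

#' @export
print.conn_matrix <- function(x, ...) {
  n <- nrow(x$r)
  cat(sprintf("<conn_matrix> subject '%s': %d nodes, %d weighted edges\n",
              x$subject, n, n * (n - 1L) / 2L))
  invisible(x)
}

#' Transform signed correlations into nonnegative edge weights
#'
#' The weighted graph measures assume nonnegative weights. `"abs"`
#' (default) keeps all 2278 edges with weight |r|, preserving edge
#' salience; `"positive"` zeroes negative correlations. The signed matrix
#' is retained separately for edge-wise statistics, which do use sign.
#'
#' @param conn a `conn_matrix` from [build_network()], or a bare symmetric
#'   correlation matrix.
#' @param transform `"abs"` or `"positive"`.
#' @return An object of class `weight_matrix`: list with `w` (nonnegative
#'   symmetric matrix, zero diagonal) and `transform`.
#' @export
to_weights <- function(conn, transform = c("abs", "positive")) {
  transform <- match.arg(transform)
  r <- if (inherits(conn, "conn_matrix")) conn$r else conn
  stopifnot(is.matrix(r), nrow(r) == ncol(r))
  w <- if (transform == "abs") abs(r) else pmax(r, 0)
  diag(w) <- 0
  structure(list(w = w, transform = transform,
                 subject = if (inherits(conn, "conn_matrix")) conn$subject
                           else NA_character_),
            class = "weight_matrix")
}

as_weight_matrix <- function(x, transform = "abs") {
  if (inherits(x, "weight_matrix")) return(x)
  if (inherits(x, "conn_matrix")) return(to_weights(x, transform))
  stopifnot(is.matrix(x))
  if (any(x < 0)) stop("negative weight: convert with to_weights() first")
  structure(list(w = x, transform = "raw", subject = NA_character_),
            class = "weight_matrix")
}

#' Export a network as an edge-list TSV
#'
#' One row per unique edge in the frozen upper-triangle row-major order,
#' with the signed correlation and the transformed weight.
#'
#' @param conn a `conn_matrix`.
#' @param path output file.
#' @param transform weight transform passed to [to_weights()].
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(conn, path, transform = "abs") {
  idx <- edge_index(conn$regions)
  w <- to_weights(conn, transform)$w
  out <- data.frame(region_a = idx$region_a, region_b = idx$region_b,
                    r = conn$r[cbind(idx$i, idx$j)],
                    w = w[cbind(idx$i, idx$j)])
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Export BrainNet-Viewer-style node and edge files
#'
#' Writes `<stem>.edge` (whitespace-separated 68 x 68 weight matrix) and
#' `<stem>.node` (x y z color size label), with node size given by
#' normalized betweenness and color by lobe index. Coordinates come from
#' the packaged synthetic centroid table.
#'
#' @param conn a `conn_matrix`.
#' @param stem output path without extension.
#' @param n_bc optional numeric vector of length 68 for node sizes
#'   (defaults to 1).
#' @param transform weight transform for the `.edge` matrix.
#' @return Character vector of the two written paths, invisibly.
#' @export
write_brainnet <- function(conn, stem, n_bc = NULL, transform = "abs") {
  atlas <- dk_atlas()
  cen <- dk_centroids()
  w <- to_weights(conn, transform)$w
  edge_path <- paste0(stem, ".edge")
  utils::write.table(format(w, digits = 6, trim = TRUE), edge_path,
                     sep = " ", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  if (is.null(n_bc)) n_bc <- rep(1, nrow(atlas))
  node <- data.frame(x = cen$x, y = cen$y, z = cen$z,
                     color = as.integer(factor(atlas$lobe)),
                     size = n_bc, label = atlas$abbrev)
  node_path <- paste0(stem, ".node")
  utils::write.table(node, node_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(c(edge_path, node_path))
}
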