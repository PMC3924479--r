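#' Construct an area adjacency graph
#'
#' The adjacency graph encodes which areas are neighbors; it underlies the
#' intrinsic CAR prior, whose conditional for area i has mean equal to the
#' average spatial effect of its `n_i` neighbors and variance
#' `sigma_S^2 / n_i`. The structure must be symmetric with no self-loops.
#' Degree-zero areas (islands) are permitted in the graph object but flagged:
#' the CAR conditional is undefined for them, and model fitting either
#' rejects them or pins their spatial effect to zero (see [run_mcmc()]).
#'
#' @param neighbors List of integer vectors, one per area, giving 1-based
#'   neighbor indices.
#' @param ids Optional character vector of area ids (defaults to indices).
#' @return An object of class `area_graph`: a list with elements `n_areas`,
#'   `neighbors`, `degrees`, `component` (1-based connected-component label
#'   per area, islands counted as their own components), `n_components`,
#'   `ids`.
#' @export
area_graph <- function(neighbors, ids = NULL) {
  n <- length(neighbors)
  neighbors <- lapply(neighbors, function(v) sort(unique(as.integer(v))))
  for (i in seq_len(n)) {
    v <- neighbors[[i]]
    if (any(v < 1 | v > n)) stop("neighbor index out of range for area ", i)
    if (i %in% v) stop("self-loop at area ", i)
    for (j in v) {
      if (!(i %in% neighbors[[j]]))
        stop("adjacency is not symmetric: ", i, " -> ", j, " but not ", j,
             " -> ", i)
    }
  }
  degrees <- vapply(neighbors, length, integer(1))
  comp <- graph_component_labels(neighbors)
  structure(
    list(n_areas = n, neighbors = neighbors, degrees = degrees,
         component = comp, n_components = max(comp),
         ids = if (is.null(ids)) as.character(seq_len(n)) else
           as.character(ids)),
    class = "area_graph")
}

# connected-component labels via igraph
graph_component_labels <- function(neighbors) {
  n <- length(neighbors)
  if (n == 1L) return(1L)
  g <- igraph::graph_from_adj_list(neighbors, mode = "all")
  as.integer(igraph::components(g)$membership)
}

#' @export
print.area_graph <- function(x, ...) {
  cat("<area_graph> ", x$n_areas, " areas, ",
      sum(x$degrees) / 2, " edges, ", x$n_components,
      " connected component(s)", sep = "")
  if (any(x$degrees == 0))
    cat(", ", sum(x$degrees == 0), " island(s)", sep = "")
  cat("\n")
  invisible(x)
}

#' Regular lattice contiguity graph
#'
#' Builds the rook (4-neighbor) or queen (8-neighbor) contiguity graph of a
#' `rows` by `cols` grid, clipped at the borders. Areas are numbered
#' row-major.
#'
#' @param rows,cols Grid dimensions; `rows * cols >= 2`.
#' @param contiguity `"rook"` or `"queen"`.
#' @return An [area_graph()].
#' @export
lattice_graph <- function(rows, cols, contiguity = c("rook", "queen")) {
  contiguity <- match.arg(contiguity)
  if (rows < 1 || cols < 1 || rows * cols < 2)
    stop("lattice must have at least 2 cells")
  idx <- function(r, c) (r - 1L) * cols + c
  off <- if (contiguity == "rook") {
    list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))
  } else {
    list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L),
         c(-1L, -1L), c(-1L, 1L), c(1L, -1L), c(1L, 1L))
  }
  nbr <- vector("list", rows * cols)
  for (r in seq_len(rows)) for (c in seq_len(cols)) {
    v <- integer(0)
    for (o in off) {
      rr <- r + o[1]; cc <- c + o[2]
      if (rr >= 1 && rr <= rows && cc >= 1 && cc <= cols)
        v <- c(v, idx(rr, cc))
    }
    nbr[[idx(r, c)]] <- v
  }
  area_graph(nbr)
}

#' Read a GAL neighbor file
#'
#' Reads GeoDa-dialect GAL files: a header line whose last-but-one-or-only
#' numeric token is the number of areas, then for each area a line
#' `"id count"` followed by a line of neighbor ids. Ids may be arbitrary
#' labels; they are mapped to indices in the order of the per-area blocks.
#' Asymmetric listings are symmetrized with a warning.
#'
#' @param path Path to a GAL file.
#' @return An [area_graph()] with `ids` taken from the file.
#' @export
read_gal <- function(path) {
  if (!file.exists(path)) stop("GAL file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  hdr <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  n <- if (length(hdr) >= 2) as.integer(hdr[2]) else as.integer(hdr[1])
  if (is.na(n) || n < 1) stop("invalid GAL header: ", lines[1])
  ids <- character(n)
  raw_nbrs <- vector("list", n)
  pos <- 2L
  for (a in seq_len(n)) {
    if (pos > length(lines)) stop("truncated GAL file at area ", a)
    head_tok <- strsplit(trimws(lines[pos]), "\\s+")[[1]]
    if (length(head_tok) < 2) stop("malformed GAL area header: ", lines[pos])
    ids[a] <- head_tok[1]
    cnt <- as.integer(head_tok[2])
    pos <- pos + 1L
    if (cnt > 0) {
      toks <- strsplit(trimws(lines[pos]), "\\s+")[[1]]
      if (length(toks) != cnt)
        stop("area '", ids[a], "' declares ", cnt, " neighbors but lists ",
             length(toks))
      raw_nbrs[[a]] <- toks
      pos <- pos + 1L
    } else {
      raw_nbrs[[a]] <- character(0)
    }
  }
  lut <- stats::setNames(seq_len(n), ids)
  nbr <- vector("list", n)
  for (a in seq_len(n)) {
    unknown <- setdiff(raw_nbrs[[a]], ids)
    if (length(unknown))
      stop("GAL file references unknown area id '", unknown[1], "'")
    nbr[[a]] <- unname(lut[raw_nbrs[[a]]])
  }
  asym <- FALSE
  for (i in seq_len(n)) for (j in nbr[[i]]) {
    if (!(i %in% nbr[[j]])) { asym <- TRUE; nbr[[j]] <- c(nbr[[j]], i) }
  }
  if (asym)
    warning("GAL adjacency was asymmetric; symmetrized by adding the ",
            "missing reciprocal links")
  area_graph(nbr, ids = ids)
}

#' Write a GAL neighbor file
#' @param graph An [area_graph()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gal <- function(graph, path) {
  stopifnot(inherits(graph, "area_graph"))
  out <- c(as.character(graph$n_areas))
  for (i in seq_len(graph$n_areas)) {
    out <- c(out, paste(graph$ids[i], graph$degrees[i]))
    if (graph$degrees[i] > 0)
      out <- c(out, paste(graph$ids[graph$neighbors[[i]]], collapse = " "))
  }
  writeLines(out, path)
  invisible(path)
}

#' Intrinsic CAR structure matrix
#'
#' Returns the ICAR structure matrix `Q = D - W` (diagonal degree matrix
#' minus the binary adjacency indicator). `Q` is symmetric positive
#' semidefinite with zero row sums; its rank is `n - c`, where `c` is the
#' number of connected components, and the improper ICAR log-density is
#' `-(n - c) log(sigma_S) - S'QS / (2 sigma_S^2)` up to a constant.
#'
#' @param graph An [area_graph()].
#' @return A dense `n x n` numeric matrix.
#' @export
icar_structure <- function(graph) {
  stopifnot(inherits(graph, "area_graph"))
  n <- graph$n_areas
  Q <- matrix(0, n, n, dimnames = list(graph$ids, graph$ids))
  for (i in seq_len(n)) {
    Q[i, i] <- graph$degrees[i]
    Q[i, graph$neighbors[[i]]] <- -1
  }
  Q
}
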