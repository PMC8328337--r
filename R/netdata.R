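#' Directed binary network
#'
#' Container for a directed graph observed as a binary adjacency matrix
#' \eqn{Y}, with \eqn{y_{ij} = 1} iff node \eqn{i} follows node \eqn{j}.
#' Self-loops are not modeled: the diagonal is forced to zero (with a
#' warning if any self-loop is present in the input).
#'
#' @param adjacency square numeric/integer matrix with entries in \{0, 1\}.
#' @param node_ids character vector of node labels; defaults to the row
#'   names of `adjacency`, or `"v1"..."vn"` when absent.
#' @return an object of class `directed_network` with elements `adjacency`
#'   (integer matrix with dimnames) and `node_ids`.
#' @export
directed_network <- function(adjacency, node_ids = NULL) {
  adjacency <- as.matrix(adjacency)
  if (nrow(adjacency) != ncol(adjacency))
    stop("adjacency must be square")
  n <- nrow(adjacency)
  if (n < 2L) stop("a directed network needs at least 2 nodes")
  if (anyNA(adjacency) || !all(adjacency %in% c(0, 1)))
    stop("adjacency entries must be 0 or 1")
  if (any(diag(adjacency) != 0)) {
    warning("self-loops found on the diagonal; dropped (y_ii = 0)")
    diag(adjacency) <- 0
  }
  if (is.null(node_ids)) node_ids <- rownames(adjacency)
  if (is.null(node_ids)) node_ids <- paste0("v", seq_len(n))
  node_ids <- as.character(node_ids)
  if (length(node_ids) != n || anyDuplicated(node_ids))
    stop("node_ids must be ", n, " unique labels")
  storage.mode(adjacency) <- "integer"
  dimnames(adjacency) <- list(node_ids, node_ids)
  structure(list(adjacency = adjacency, node_ids = node_ids),
            class = "directed_network")
}

#' @export
print.directed_network <- function(x, ...) {
  m <- sum(x$adjacency)
  n <- length(x$node_ids)
  cat(sprintf("directed_network: %d nodes, %d directed edges (density %.4f)\n",
              n, m, m / (n * (n - 1))))
  invisible(x)
}

n_nodes <- function(net) length(net$node_ids)

#' Read a directed network from disk
#'
#' Accepts either a two-column edge list (source, target; one directed edge
#' per line, optional header) or a square 0/1 adjacency matrix in CSV form
#' with node ids as header row and first column. Duplicate edges are
#' collapsed; self-loops are dropped with a warning.
#'
#' @param path file path.
#' @param format `"auto"` (default), `"edgelist"` or `"adjacency"`.
#' @param node_ids optional explicit node universe for edge lists; an edge
#'   referencing an unknown id is then an error.
#' @param sep field separator; guessed from the extension when `NULL`
#'   (`","` for `.csv`, whitespace/tab otherwise).
#' @return a [directed_network()].
#' @export
read_network <- function(path, format = c("auto", "edgelist", "adjacency"),
                         node_ids = NULL, sep = NULL) {
  format <- match.arg(format)
  if (is.null(sep))
    sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else ""
  if (format == "auto") {
    first <- readLines(path, n = 1L)
    nf <- length(strsplit(trimws(first),
                          if (sep == "") "[ \t]+" else sep)[[1]])
    format <- if (nf > 2L) "adjacency" else "edgelist"
  }
  if (format == "adjacency") {
    tab <- utils::read.table(path, header = TRUE, sep = sep,
                             row.names = 1L, check.names = FALSE)
    mat <- as.matrix(tab)
    if (!all(mat %in% c(0, 1)))
      stop("adjacency file contains non-binary entries")
    return(directed_network(mat, node_ids = rownames(tab)))
  }
  el <- utils::read.table(path, header = FALSE, sep = sep,
                          colClasses = "character",
                          blank.lines.skip = TRUE)
  if (ncol(el) < 2L) stop("edge list must have two columns")
  # tolerate a header line like "from<TAB>to"
  if (nrow(el) > 1L && all(tolower(unlist(el[1, 1:2])) %in%
                           c("from", "to", "source", "target", "src", "dst")))
    el <- el[-1L, , drop = FALSE]
  src <- el[[1L]]; dst <- el[[2L]]
  ids <- if (is.null(node_ids)) sort(unique(c(src, dst))) else as.character(node_ids)
  unknown <- setdiff(unique(c(src, dst)), ids)
  if (length(unknown))
    stop("edge references unknown node id(s): ",
         paste(unknown, collapse = ", "))
  n <- length(ids)
  Y <- matrix(0L, n, n, dimnames = list(ids, ids))
  i <- match(src, ids); j <- match(dst, ids)
  loops <- i == j
  if (any(loops)) {
    warning(sum(loops), " self-loop(s) dropped")
    i <- i[!loops]; j <- j[!loops]
  }
  Y[cbind(i, j)] <- 1L  # duplicates collapse
  directed_network(Y, node_ids = ids)
}

#' Write a network as an edge-list TSV
#' @param net a [directed_network()].
#' @param path output file.
#' @export
write_edgelist <- function(net, path) {
  idx <- which(net$adjacency == 1L, arr.ind = TRUE)
  el <- data.frame(from = net$node_ids[idx[, 1]],
                   to = net$node_ids[idx[, 2]])
  utils::write.table(el[order(el$from, el$to), ], path, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' In/out degrees and popular hubs
#'
#' In-degrees are column sums of \eqn{Y} (\eqn{d_j^{in} = \sum_i y_{ij}}),
#' out-degrees are row sums. The `n_hubs` nodes with the largest in-degrees
#' are designated popular hubs (ties broken deterministically by lower node
#' index).
#'
#' @param net a [directed_network()].
#' @param n_hubs number of hubs to designate (default 5, the convention for
#'   the simulation studies; 0 for none).
#' @return a `degree_summary` list with `d_in`, `d_out`, `hub_set` (integer
#'   node indices) and `n_hubs`.
#' @export
degrees <- function(net, n_hubs = 5L) {
  Y <- net$adjacency
  n <- nrow(Y)
  n_hubs <- as.integer(n_hubs)
  if (n_hubs < 0L || n_hubs > n) stop("n_hubs must be in [0, n]")
  d_in <- colSums(Y)
  d_out <- rowSums(Y)
  hub_set <- if (n_hubs > 0L)
    order(d_in, seq_len(n), decreasing = c(TRUE, FALSE), method = "radix")[seq_len(n_hubs)]
  else integer(0)
  structure(list(d_in = d_in, d_out = d_out,
                 hub_set = hub_set, n_hubs = n_hubs),
            class = "degree_summary")
}

#' Pairwise homophily covariates from node attributes
#'
#' Builds the symmetric, non-negative pair-specific covariates used in the
#' model's log-odds. Continuous attributes are min-max rescaled column-wise
#' to \[epsilon, 1\] and then transformed to the absolute log-difference
#' \eqn{x_{ij} = |\log a_i - \log a_j|}; categorical (incl. binary)
#' attributes give the same-category indicator
#' \eqn{x_{ij} = 1\{a_i \ne a_j\}}.
#'
#' @param attrs data.frame of node attributes, one row per node, row order
#'   matching the network's node order. Must be complete (no `NA`).
#' @param types optional character vector (`"continuous"`/`"categorical"`),
#'   one per column; inferred when `NULL` (numeric with > 2 distinct values
#'   is continuous, everything else categorical).
#' @param epsilon lower end of the min-max rescaling (default `1e-3`); keeps
#'   the log transform finite at the column minimum.
#' @return a `pairwise_covariates` object: list with `X` (an
#'   `n x n x p` array, diagonal slices zero), `names`, `types`.
#' @export
pairwise_covariates <- function(attrs, types = NULL, epsilon = 1e-3) {
  attrs <- as.data.frame(attrs)
  if (anyNA(attrs))
    stop("attribute table contains missing values; drop incomplete rows first")
  if (epsilon <= 0 || epsilon >= 1) stop("epsilon must be in (0, 1)")
  n <- nrow(attrs)
  p <- ncol(attrs)
  if (is.null(types)) {
    types <- vapply(attrs, function(a) {
      if (is.numeric(a) && length(unique(a)) > 2L) "continuous" else "categorical"
    }, character(1))
  }
  types <- rep_len(types, p)
  if (!all(types %in% c("continuous", "categorical")))
    stop("types must be 'continuous' or 'categorical'")
  X <- array(0, dim = c(n, n, max(p, 1L)))
  for (k in seq_len(p)) {
    a <- attrs[[k]]
    if (types[k] == "continuous") {
      if (!is.numeric(a) || any(!is.finite(a)))
        stop("continuous column '", names(attrs)[k], "' must be finite numeric")
      rng <- range(a)
      if (diff(rng) == 0)
        stop("continuous column '", names(attrs)[k],
             "' is constant (zero range); cannot normalize")
      s <- epsilon + (1 - epsilon) * (a - rng[1]) / diff(rng)
      X[, , k] <- abs(outer(log(s), log(s), "-"))
    } else {
      lab <- as.character(a)
      X[, , k] <- 1 * outer(lab, lab, "!=")
    }
  }
  if (p == 0L) X <- array(0, dim = c(n, n, 0L))
  structure(list(X = X, names = names(attrs), types = types,
                 epsilon = epsilon),
            class = "pairwise_covariates")
}

#' Read a node attribute table
#'
#' CSV with the node id in the first column. Rows are reordered to match
#' the network's node ids when `net` is given; ids without an attribute row
#' raise an error listing them.
#'
#' @param path CSV file path.
#' @param net optional [directed_network()] to align against.
#' @return data.frame with node ids as row names.
#' @export
read_attributes <- function(path, net = NULL) {
  tab <- utils::read.csv(path, check.names = FALSE,
                         stringsAsFactors = FALSE)
  ids <- as.character(tab[[1L]])
  tab <- tab[, -1L, drop = FALSE]
  rownames(tab) <- ids
  if (!is.null(net)) {
    missing_ids <- setdiff(net$node_ids, ids)
    if (length(missing_ids))
      stop("attribute rows missing for node id(s): ",
           paste(missing_ids, collapse = ", "))
    tab <- tab[net$node_ids, , drop = FALSE]
  }
  tab
}

#' Drop nodes with incomplete attributes
#'
#' Restricts a network and its attribute table to the nodes whose attribute
#' rows are complete, mirroring the usual preprocessing of social-network
#' profile data before modeling.
#'
#' @param net a [directed_network()].
#' @param attrs attribute data.frame aligned to `net$node_ids`.
#' @return list with the subset `net` and `attrs`.
#' @export
drop_incomplete <- function(net, attrs) {
  keep <- stats::complete.cases(attrs)
  if (all(keep)) return(list(net = net, attrs = attrs))
  ids <- net$node_ids[keep]
  list(net = directed_network(net$adjacency[keep, keep, drop = FALSE],
                              node_ids = ids),
       attrs = attrs[keep, , drop = FALSE])
}

#' Empirical link probabilities
#'
#' The four empirical statistics summarizing sparsity and reciprocity of a
#' directed network:
#' \itemize{
#'   \item `p_link`: marginal \eqn{\hat P(y_{ij}=1) = \sum y_{ij} / (n(n-1))}
#'   \item `p_mutual`: \eqn{\hat P(y_{ij} y_{ji}=1) = \sum y_{ij}y_{ji} / (n(n-1))}
#'   \item `p_recip`: conditional reciprocity
#'     \eqn{\hat P(y_{ji}=1 \mid y_{ij}=1) = \sum y_{ij}y_{ji} / \sum y_{ij}}
#'   \item `p_recip_hub`: reciprocity of edges sent to popular hubs,
#'     \eqn{\hat P(y_{j^*i}=1 \mid y_{ij^*}=1)} with \eqn{j^*} ranging over
#'     the hub set.
#' }
#' Conditional statistics whose denominator is zero are returned as `NaN`
#' and listed in the `undefined` field.
#'
#' @param net a [directed_network()].
#' @param degs optional [degrees()] summary (computed with its defaults when
#'   `NULL`); its `hub_set` defines the hub-conditional statistic.
#' @return list `p_link`, `p_mutual`, `p_recip`, `p_recip_hub`, `undefined`.
#' @export
empirical_link_stats <- function(net, degs = NULL) {
  Y <- net$adjacency
  n <- nrow(Y)
  if (is.null(degs)) degs <- degrees(net, n_hubs = min(5L, n))
  npairs <- n * (n - 1)
  m <- sum(Y)
  mut <- sum(Y * t(Y))
  p_link <- m / npairs
  p_mutual <- mut / npairs
  undefined <- character(0)
  if (m > 0) p_recip <- mut / m else { p_recip <- NaN; undefined <- c(undefined, "p_recip") }
  hubs <- degs$hub_set
  if (length(hubs) == 0L) {
    p_recip_hub <- NaN; undefined <- c(undefined, "p_recip_hub")
  } else {
    sent_to_hubs <- sum(Y[, hubs, drop = FALSE])
    returned <- sum(Y[, hubs, drop = FALSE] * t(Y[hubs, , drop = FALSE]))
    if (sent_to_hubs > 0) p_recip_hub <- returned / sent_to_hubs
    else { p_recip_hub <- NaN; undefined <- c(undefined, "p_recip_hub") }
  }
  list(p_link = p_link, p_mutual = p_mutual, p_recip = p_recip,
       p_recip_hub = p_recip_hub, undefined = undefined)
}

#' Complementary CDF of a degree sequence with a log-log tail fit
#'
#' Returns \eqn{P(\mathrm{degree} \ge k)} at every observed degree value,
#' and the least-squares slope of log CCDF against log degree restricted to
#' a caller-supplied degree window (power-law degrees give an approximately
#' linear CCDF on log-log axes, with slope \eqn{-(\theta - 1)}).
#'
#' @param degs a [degrees()] summary.
#' @param side `"in"` or `"out"`.
#' @param fit_range numeric length-2 degree window `c(lo, hi)` for the
#'   slope fit; `NULL` uses all positive observed degrees.
#' @return list `degree`, `ccdf`, `slope`, `fit` (the `lm` object).
#' @export
degree_ccdf <- function(degs, side = c("in", "out"), fit_range = NULL) {
  side <- match.arg(side)
  d <- if (side == "in") degs$d_in else degs$d_out
  if (all(d == 0)) stop("all degrees are zero; CCDF undefined on log scale")
  ks <- sort(unique(d))
  ccdf <- vapply(ks, function(k) mean(d >= k), numeric(1))
  keep <- ks > 0
  if (!is.null(fit_range))
    keep <- keep & ks >= fit_range[1] & ks <= fit_range[2]
  if (sum(keep) < 2L) {
    if (!is.null(fit_range))
      stop("fewer than 2 points in the CCDF fit window")
    return(list(degree = ks, ccdf = ccdf, slope = NA_real_, fit = NULL))
  }
  fit <- stats::lm(log(ccdf[keep]) ~ log(ks[keep]))
  list(degree = ks, ccdf = ccdf,
       slope = unname(stats::coef(fit)[2]), fit = fit)
}
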