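## Heterogeneous-network data model, dense-text matrix I/O, validation,
## and construction of the row-stochastic transition matrix for the walk.

NODE_TYPES <- c("drug", "protein", "disease", "side_effect")

#' Node space of a heterogeneous network
#'
#' Defines the four node populations (drugs, proteins/targets, diseases,
#' side effects) and the fixed global index layout: contiguous blocks in
#' the order drug, protein, disease, side_effect. Every embedding matrix
#' in the package uses this row order.
#'
#' @param counts named integer vector or list with entries `drug`,
#'   `protein`, `disease`, `side_effect`, all >= 1.
#' @return An object of class `node_space` with elements `types`, `counts`,
#'   `offsets` (0-based block offsets) and `n` (total node count).
#' @examples
#' sp <- node_space(c(drug = 3, protein = 4, disease = 2, side_effect = 2))
#' sp$n
#' @export
node_space <- function(counts) {
  counts <- unlist(counts)
  if (!all(NODE_TYPES %in% names(counts)))
    fail("counts must name all of: %s", paste(NODE_TYPES, collapse = ", "))
  counts <- counts[NODE_TYPES]
  if (!all(vapply(counts, is_count, logical(1))))
    fail("all node-type counts must be positive integers")
  counts <- as.integer(counts)
  names(counts) <- NODE_TYPES
  offsets <- c(0L, cumsum(counts)[-length(counts)])
  names(offsets) <- NODE_TYPES
  structure(list(types = NODE_TYPES, counts = counts, offsets = offsets,
                 n = sum(counts)),
            class = "node_space")
}

#' Global row indices of one node-type block
#'
#' @param space a `node_space`.
#' @param type node-type name.
#' @return Integer vector of global (1-based) indices.
#' @export
block_index <- function(space, type) {
  stopifnot(inherits(space, "node_space"))
  if (!type %in% space$types) fail("unknown node type '%s'", type)
  space$offsets[[type]] + seq_len(space$counts[[type]])
}

#' Edge-type metadata
#'
#' Describes one of the relation networks: endpoints, whether values are
#' binary associations or real similarities in `[0,1]`, whether the matrix
#' is symmetric, and whether its edges take part in the random walk (the
#' two similarity edge types are excluded from the walk).
#'
#' @param name identifier for the edge type.
#' @param src_type,dst_type node-type names of rows and columns.
#' @param value_kind `"binary"` or `"real_unit_interval"`.
#' @param symmetric logical; only allowed when `src_type == dst_type`.
#' @return An object of class `edge_type_spec`.
#' @export
edge_type_spec <- function(name, src_type, dst_type,
                           value_kind = c("binary", "real_unit_interval"),
                           symmetric = src_type == dst_type) {
  value_kind <- match.arg(value_kind)
  if (!src_type %in% NODE_TYPES || !dst_type %in% NODE_TYPES)
    fail("edge type '%s': unknown node type", name)
  if (symmetric && src_type != dst_type)
    fail("edge type '%s': symmetric requires src_type == dst_type", name)
  structure(list(name = name, src_type = src_type, dst_type = dst_type,
                 value_kind = value_kind, symmetric = symmetric,
                 in_walk = value_kind == "binary"),
            class = "edge_type_spec")
}

#' The eight standard edge types of the DTI benchmark layout
#'
#' Six binary association/interaction networks (drug-target, drug-drug,
#' protein-protein, drug-disease, drug-side-effect, protein-disease) and
#' two real-valued similarity networks (drug chemical-structure similarity,
#' protein sequence similarity). Only the binary networks enter the random
#' walk.
#'
#' @return Named list of `edge_type_spec` objects.
#' @export
default_edge_types <- function() {
  specs <- list(
    edge_type_spec("drug_target",     "drug",    "protein"),
    edge_type_spec("drug_drug",       "drug",    "drug"),
    edge_type_spec("protein_protein", "protein", "protein"),
    edge_type_spec("drug_disease",    "drug",    "disease"),
    edge_type_spec("drug_se",         "drug",    "side_effect"),
    edge_type_spec("protein_disease", "protein", "disease"),
    edge_type_spec("drug_sim",        "drug",    "drug",
                   value_kind = "real_unit_interval"),
    edge_type_spec("protein_sim",     "protein", "protein",
                   value_kind = "real_unit_interval")
  )
  names(specs) <- vapply(specs, `[[`, character(1), "name")
  specs
}

#' Assemble a heterogeneous network
#'
#' @param space a `node_space`.
#' @param edges named list of `edge_type_spec`.
#' @param matrices named list of matrices, one per edge type, each of shape
#'   `counts[src_type] x counts[dst_type]`.
#' @param validate validate invariants and fail on violations (default TRUE).
#' @return An object of class `hetero_network`.
#' @export
hetero_network <- function(space, edges, matrices, validate = TRUE) {
  stopifnot(inherits(space, "node_space"))
  if (!setequal(names(edges), names(matrices)))
    fail("edges and matrices must cover the same edge-type names")
  matrices <- matrices[names(edges)]
  net <- structure(list(space = space, edges = edges, matrices = matrices),
                   class = "hetero_network")
  if (validate) {
    rep <- validate_network(net)
    if (nrow(rep) > 0L)
      fail("invalid network: %s", paste(rep$message, collapse = "; "))
  }
  net
}

#' @export
print.hetero_network <- function(x, ...) {
  cat("Heterogeneous network:",
      paste(sprintf("%d %ss", x$space$counts, sub("_", " ", x$space$types)),
            collapse = ", "), "\n")
  for (nm in names(x$edges)) {
    e <- x$edges[[nm]]
    m <- x$matrices[[nm]]
    cat(sprintf("  %-16s %s x %s  [%s%s]  %s\n", nm, e$src_type, e$dst_type,
                e$value_kind, if (e$symmetric) ", symmetric" else "",
                if (e$value_kind == "binary")
                  sprintf("%d edges", as.integer(sum(m)))
                else sprintf("mean %.3f", mean(m))))
  }
  invisible(x)
}

#' Validate the invariants of a heterogeneous network
#'
#' Checks matrix shapes against the node space, non-negativity, strict
#' `{0,1}` content of binary matrices, `[0,1]` range and unit diagonal of
#' similarity matrices, and symmetry of symmetric edge types. Violations
#' are returned as data, never raised.
#'
#' @param net a `hetero_network`.
#' @param tol symmetry/diagonal tolerance.
#' @return A data frame with columns `edge_type`, `rule`, `row`, `col`,
#'   `message`; zero rows when the network is valid.
#' @export
validate_network <- function(net, tol = 1e-9) {
  viol <- list()
  add <- function(edge, rule, row, col, msg)
    viol[[length(viol) + 1L]] <<- data.frame(
      edge_type = edge, rule = rule, row = row, col = col, message = msg,
      stringsAsFactors = FALSE)

  sp <- net$space
  for (nm in names(net$edges)) {
    e <- net$edges[[nm]]
    m <- net$matrices[[nm]]
    want <- c(sp$counts[[e$src_type]], sp$counts[[e$dst_type]])
    if (!is.matrix(m) || !all(dim(m) == want)) {
      add(nm, "shape", NA, NA,
          sprintf("%s: expected %dx%d, got %s", nm, want[1], want[2],
                  paste(dim(m), collapse = "x")))
      next
    }
    bad <- which(m < 0, arr.ind = TRUE)
    if (nrow(bad) > 0L)
      add(nm, "negative", bad[1, 1], bad[1, 2],
          sprintf("%s: negative value at (%d,%d)", nm, bad[1, 1], bad[1, 2]))
    if (e$value_kind == "binary") {
      off <- which(abs(m) > tol & abs(m - 1) > tol, arr.ind = TRUE)
      if (nrow(off) > 0L)
        add(nm, "non_binary", off[1, 1], off[1, 2],
            sprintf("%s: non-binary value %g at (%d,%d)", nm,
                    m[off[1, 1], off[1, 2]], off[1, 1], off[1, 2]))
    } else {
      out <- which(m < -tol | m > 1 + tol, arr.ind = TRUE)
      if (nrow(out) > 0L)
        add(nm, "unit_interval", out[1, 1], out[1, 2],
            sprintf("%s: similarity %g outside [0,1] at (%d,%d)", nm,
                    m[out[1, 1], out[1, 2]], out[1, 1], out[1, 2]))
      if (nrow(m) == ncol(m)) {
        dbad <- which(abs(diag(m) - 1) > tol)
        if (length(dbad) > 0L)
          add(nm, "unit_diagonal", dbad[1], dbad[1],
              sprintf("%s: diagonal %g != 1 at node %d", nm,
                      m[dbad[1], dbad[1]], dbad[1]))
      }
    }
    if (e$symmetric && nrow(m) == ncol(m)) {
      d <- abs(m - t(m))
      if (max(d) > tol) {
        ij <- which(d == max(d), arr.ind = TRUE)[1, ]
        add(nm, "symmetry", ij[1], ij[2],
            sprintf("%s: asymmetric at (%d,%d): %g vs %g", nm, ij[1], ij[2],
                    m[ij[1], ij[2]], m[ij[2], ij[1]]))
      }
    }
  }
  if (length(viol) == 0L)
    data.frame(edge_type = character(), rule = character(),
               row = integer(), col = integer(), message = character(),
               stringsAsFactors = FALSE)
  else do.call(rbind, viol)
}

read_dense_matrix <- function(path, nrow, ncol) {
  vals <- scan(path, what = double(), quiet = TRUE)
  if (length(vals) != nrow * ncol)
    fail("%s: expected %d x %d = %d values, found %d", path, nrow, ncol,
         nrow * ncol, length(vals))
  matrix(vals, nrow = nrow, ncol = ncol, byrow = TRUE)
}

snap_binary <- function(m, name, tol = 1e-9) {
  near0 <- abs(m) <= tol
  near1 <- abs(m - 1) <= tol
  bad <- which(!(near0 | near1), arr.ind = TRUE)
  if (nrow(bad) > 0L)
    fail("edge type '%s': non-binary value %g at (%d,%d)", name,
         m[bad[1, 1], bad[1, 2]], bad[1, 1], bad[1, 2])
  out <- matrix(0, nrow(m), ncol(m))
  out[near1] <- 1
  out
}

#' Load a heterogeneous network from a manifest
#'
#' The manifest is a JSON file declaring node-type counts and, per edge
#' type, the matrix file path (relative paths resolve against the manifest
#' directory) and metadata. Matrix files are dense whitespace-delimited
#' text, one row per source node. Binary matrices are snapped from values
#' within `1e-9` of 0/1; anything else errors with the offending cell.
#'
#' @param manifest_path path to the manifest JSON.
#' @return A validated `hetero_network`.
#' @seealso [write_network()] for the inverse.
#' @export
load_network <- function(manifest_path) {
  if (!file.exists(manifest_path)) fail("manifest not found: %s", manifest_path)
  man <- jsonlite::fromJSON(manifest_path, simplifyDataFrame = FALSE)
  if (is.null(man$counts) || is.null(man$edges))
    fail("manifest must contain 'counts' and 'edges'")
  space <- node_space(man$counts)
  dir <- dirname(normalizePath(manifest_path))

  edges <- list(); matrices <- list()
  for (ed in man$edges) {
    spec <- edge_type_spec(ed$name, ed$src_type, ed$dst_type,
                           value_kind = ed$value_kind,
                           symmetric = isTRUE(ed$symmetric))
    path <- ed$file
    if (!grepl("^(/|[A-Za-z]:)", path)) path <- file.path(dir, path)
    if (!file.exists(path)) fail("matrix file not found: %s", path)
    m <- read_dense_matrix(path, space$counts[[spec$src_type]],
                           space$counts[[spec$dst_type]])
    if (spec$value_kind == "binary") m <- snap_binary(m, spec$name)
    edges[[spec$name]] <- spec
    matrices[[spec$name]] <- m
  }
  net <- hetero_network(space, edges, matrices, validate = FALSE)
  rep <- validate_network(net)
  if (nrow(rep) > 0L)
    fail("invalid network in %s: %s", manifest_path,
         paste(rep$message, collapse = "; "))
  net
}

#' Write a heterogeneous network as manifest + dense text matrices
#'
#' Produces the same dialect [load_network()] reads: one whitespace-
#' delimited text file per edge type plus `manifest.json`. Binary values
#' are written as integers; similarities at full double precision, so a
#' round trip is bit-exact for binary matrices and within 1e-12 for
#' similarities.
#'
#' @param net a `hetero_network`.
#' @param dir output directory (created if needed).
#' @param manifest manifest file name.
#' @return Invisibly, the manifest path.
#' @export
write_network <- function(net, dir, manifest = "manifest.json") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  edges <- lapply(names(net$edges), function(nm) {
    e <- net$edges[[nm]]
    file <- paste0("mat_", nm, ".txt")
    m <- net$matrices[[nm]]
    lines <- if (e$value_kind == "binary")
      apply(m, 1, function(r) paste(as.integer(r), collapse = " "))
    else
      apply(m, 1, function(r) paste(formatC(r, format = "g", digits = 17),
                                    collapse = " "))
    writeLines(lines, file.path(dir, file))
    list(name = e$name, file = file, src_type = e$src_type,
         dst_type = e$dst_type, value_kind = e$value_kind,
         symmetric = e$symmetric)
  })
  man <- list(counts = as.list(net$space$counts), edges = edges)
  path <- file.path(dir, manifest)
  jsonlite::write_json(man, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Build the row-stochastic transition matrix for the random walk
#'
#' Assembles the global symmetric adjacency over all walk-eligible edge
#' types (the binary networks; similarity edges are deleted before the
#' walk), placing each cross-type block in both orientations, then divides
#' each row by its sum. Nodes with no walk-eligible edges get a unit
#' self-loop so their features are preserved exactly under restart.
#'
#' @param net a `hetero_network`.
#' @return A sparse row-stochastic `Matrix::dgCMatrix` over the global
#'   node index.
#' @export
build_transition_matrix <- function(net) {
  sp <- net$space
  n <- sp$n
  A <- Matrix::Matrix(0, n, n, sparse = TRUE)
  for (nm in names(net$edges)) {
    e <- net$edges[[nm]]
    if (!e$in_walk) next
    i <- block_index(sp, e$src_type)
    j <- block_index(sp, e$dst_type)
    m <- Matrix::Matrix(net$matrices[[nm]], sparse = TRUE)
    A[i, j] <- A[i, j] + m
    if (e$src_type != e$dst_type) A[j, i] <- A[j, i] + Matrix::t(m)
    else if (!e$symmetric) A[i, j] <- A[i, j] + Matrix::t(m) # defensive; walk graph is undirected
  }
  rs <- Matrix::rowSums(A)
  dangling <- which(rs == 0)
  inv <- ifelse(rs > 0, 1 / rs, 0)
  A <- Matrix::Diagonal(x = inv) %*% A
  if (length(dangling) > 0L)
    A <- A + Matrix::sparseMatrix(i = dangling, j = dangling,
                                  x = rep(1, length(dangling)),
                                  dims = c(n, n))
  methods::as(A, "CsparseMatrix")
}
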