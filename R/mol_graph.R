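## Hydrogen-suppressed molecular graphs from SMILES.
##
## SMILES conversion is delegated to ChemmineR/ChemmineOB (OpenBabel).
## The resulting connection table (kekulized bond orders) is augmented
## with implicit-hydrogen counts from a standard valence model and with
## aromatic bond flags from ChemmineR's ring perception; all topological
## descriptors are computed on this graph.  The catalogue targets
## neutral organic molecules (C, N, O, S, P, halogens, B, Si); formal
## charges are not modeled.

## smallest standard valence >= bond-order sum
.std_valences <- list(
  H = 1, B = 3, C = 4, N = c(3, 5), O = 2, F = 1,
  Si = 4, P = c(3, 5), S = c(2, 4, 6), Cl = 1, Br = 1, I = 1
)

## valence electron counts
.n_outer <- c(H = 1, B = 3, C = 4, N = 5, O = 6, F = 7,
              Si = 4, P = 5, S = 6, Cl = 7, Br = 7, I = 7)

.atomic_number <- c(H = 1, B = 5, C = 6, N = 7, O = 8, F = 9,
                    Si = 14, P = 15, S = 16, Cl = 17, Br = 35, I = 53)

## rdkit Rb0 radii (angstrom), used by the Labute surface-area scheme
.rb0 <- c(H = 0.33, B = 0.84, C = 0.77, N = 0.70, O = 0.66, F = 0.611,
          Si = 1.17, P = 0.89, S = 1.04, Cl = 0.997, Br = 1.167, I = 1.387)

.implicit_h <- function(elem, bond_order_sum) {
  vals <- .std_valences[[elem]]
  if (is.null(vals)) return(0L)
  ok <- vals[vals >= bond_order_sum]
  if (!length(ok)) return(0L)
  as.integer(ok[1L] - bond_order_sum)
}

#' Parse SMILES into hydrogen-suppressed molecular graphs
#'
#' Converts SMILES to a connection table via ChemmineR (OpenBabel
#' backend), then derives per-atom implicit-hydrogen counts, Kier-Hall
#' valence deltas, adjacency and topological distance matrices, and
#' aromatic bond flags.
#'
#' @param smiles character vector of SMILES strings.
#' @return A list of `mol_graph` objects (one per input), each with
#'   elements `atoms` (data.frame: `elem`, `nH`, `degree`, `delta_v`),
#'   `bonds` (data.frame: `i`, `j`, `order`, `aromatic`), `A` (adjacency
#'   matrix) and `D` (topological distance matrix).  Unparseable SMILES
#'   raise an error naming the offending input.
#' @export
parse_smiles <- function(smiles) {
  stopifnot(is.character(smiles), length(smiles) >= 1L)
  if (!requireNamespace("ChemmineOB", quietly = TRUE)) {
    stop("ChemmineOB is required for SMILES parsing", call. = FALSE)
  }
  out <- vector("list", length(smiles))
  for (k in seq_along(smiles)) {
    sdf <- tryCatch(
      suppressWarnings(ChemmineR::smiles2sdf(smiles[k]))[[1L]],
      error = function(e) NULL)
    ab_ok <- !is.null(sdf) &&
      nrow(ChemmineR::atomblock(sdf)) > 0L &&
      all(sub("_.*$", "", rownames(ChemmineR::atomblock(sdf))) %in%
            c(names(.atomic_number), "H"))
    out[[k]] <- if (ab_ok) {
      .graph_from_sdf(sdf)
    } else {
      ## the SDF reader mis-handles bond-free (single heavy atom)
      ## molecules; recover the element from the raw V2000 block
      .single_atom_graph(smiles[k], k)
    }
  }
  out
}

.single_atom_graph <- function(smi, pos) {
  txt <- tryCatch(
    ChemmineOB::convertFormat("SMI", "SDF", paste0(smi, "\n")),
    error = function(e) "")
  lines <- strsplit(txt, "\n", fixed = TRUE)[[1L]]
  counts <- if (length(lines) >= 4L) lines[4L] else ""
  natoms <- suppressWarnings(as.integer(substr(counts, 1L, 3L)))
  if (is.na(natoms) || natoms != 1L) {
    stop("unparseable SMILES at position ", pos, ": '", smi, "'",
         call. = FALSE)
  }
  elem <- trimws(substr(lines[5L], 32L, 34L))
  if (!elem %in% names(.atomic_number)) {
    stop("unsupported element '", elem, "' in SMILES at position ", pos,
         call. = FALSE)
  }
  nH <- .implicit_h(elem, 0)
  Zv <- .n_outer[[elem]]; Z <- .atomic_number[[elem]]
  dv <- if (Z <= 10) Zv - nH else (Zv - nH) / (Z - Zv - 1)
  structure(list(
    atoms = data.frame(elem = elem, nH = as.integer(nH), degree = 0L,
                       delta_v = as.numeric(dv)),
    bonds = data.frame(i = integer(), j = integer(), order = integer(),
                       aromatic = logical()),
    A = matrix(0L, 1L, 1L), D = matrix(0, 1L, 1L)
  ), class = "mol_graph")
}

.graph_from_sdf <- function(sdf) {
  ab <- ChemmineR::atomblock(sdf)
  bb <- ChemmineR::bondblock(sdf)
  elems <- sub("_.*$", "", rownames(ab))
  n <- length(elems)

  ## strip explicit hydrogens (e.g. pyrrole NH written out by the
  ## converter): count them on their heavy neighbor instead
  remap <- seq_len(n)
  extra_h <- integer(n)
  if (any(elems == "H") && !is.null(dim(bb)) && nrow(bb) > 0L) {
    hidx <- which(elems == "H")
    for (h in hidx) {
      nb <- c(bb[bb[, 1L] == h, 2L], bb[bb[, 2L] == h, 1L])
      for (x in nb) extra_h[x] <- extra_h[x] + 1L
    }
    keep <- setdiff(seq_len(n), hidx)
    remap <- rep(NA_integer_, n)
    remap[keep] <- seq_along(keep)
    bb <- bb[!(bb[, 1L] %in% hidx | bb[, 2L] %in% hidx), , drop = FALSE]
    bb[, 1L] <- remap[bb[, 1L]]
    bb[, 2L] <- remap[bb[, 2L]]
    elems <- elems[keep]
    extra_h <- extra_h[keep]
    n <- length(elems)
  }
  unknown <- setdiff(unique(elems), names(.atomic_number))
  if (length(unknown)) {
    stop("unsupported element(s) in molecule: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }

  bonds <- if (is.null(dim(bb)) || nrow(bb) == 0L) {
    data.frame(i = integer(), j = integer(), order = integer())
  } else {
    data.frame(i = as.integer(bb[, 1L]), j = as.integer(bb[, 2L]),
               order = as.integer(bb[, 3L]))
  }

  ## aromatic flags from ring perception (kekulized orders retained)
  bonds$aromatic <- FALSE
  if (nrow(bonds) > 0L && n >= 3L) {
    rr <- tryCatch(ChemmineR::rings(sdf, type = "all", arom = TRUE),
                   error = function(e) NULL)
    if (!is.null(rr) && length(rr$RINGS)) {
      arom_rings <- rr$RINGS[rr$AROMATIC]
      if (length(arom_rings)) {
        key <- paste(pmin(bonds$i, bonds$j), pmax(bonds$i, bonds$j))
        for (ring in arom_rings) {
          idx <- remap[as.integer(sub("^.*_", "", ring))]
          if (anyNA(idx)) next
          m <- length(idx)
          ri <- idx
          rj <- idx[c(2:m, 1L)]
          rkey <- paste(pmin(ri, rj), pmax(ri, rj))
          bonds$aromatic[key %in% rkey] <- TRUE
        }
      }
    }
  }

  A <- matrix(0L, n, n)
  if (nrow(bonds) > 0L) {
    A[cbind(bonds$i, bonds$j)] <- 1L
    A[cbind(bonds$j, bonds$i)] <- 1L
  }
  degree <- rowSums(A)

  bond_sum <- numeric(n)
  if (nrow(bonds) > 0L) {
    for (b in seq_len(nrow(bonds))) {
      bond_sum[bonds$i[b]] <- bond_sum[bonds$i[b]] + bonds$order[b]
      bond_sum[bonds$j[b]] <- bond_sum[bonds$j[b]] + bonds$order[b]
    }
  }
  ## explicit hydrogens seen in the connection table suppress implicit
  ## ones: the converter writes them out exactly where they are not
  ## inferable from the standard valence model
  nH <- ifelse(extra_h > 0, extra_h, mapply(.implicit_h, elems, bond_sum))

  Zv <- .n_outer[elems]
  Z <- .atomic_number[elems]
  ## Kier-Hall valence delta: Zv - nH for second-row atoms,
  ## (Zv - nH)/(Z - Zv - 1) below
  delta_v <- ifelse(Z <= 10, Zv - nH, (Zv - nH) / (Z - Zv - 1))

  D <- .bfs_distances(A)
  structure(list(
    atoms = data.frame(elem = elems, nH = as.integer(nH),
                       degree = as.integer(degree),
                       delta_v = as.numeric(delta_v),
                       row.names = NULL),
    bonds = bonds, A = A, D = D
  ), class = "mol_graph")
}

## all-pairs shortest path lengths on an unweighted graph
.bfs_distances <- function(A) {
  n <- nrow(A)
  D <- matrix(Inf, n, n)
  diag(D) <- 0
  reach <- diag(n) > 0
  Ak <- diag(n)
  for (k in seq_len(max(1L, n - 1L))) {
    Ak <- (Ak %*% A) > 0
    new <- Ak & !reach
    if (!any(new)) break
    D[new] <- k
    reach <- reach | new
  }
  D
}

#' @export
print.mol_graph <- function(x, ...) {
  cat(sprintf("mol_graph: %d heavy atoms, %d bonds (%s)\n",
              nrow(x$atoms), nrow(x$bonds),
              paste0(names(sort(-table(x$atoms$elem))), collapse = "")))
  invisible(x)
}
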