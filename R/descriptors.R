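## Topological descriptor catalogue.
##
## Native implementations of the graph-theoretic molecular descriptors
## used by the learned solubility model: valence-weighted Chi path
## indices (Xp-n-dv), the ETA core count (ETA_alpha), Galvez mean
## topological charge indices (JGIn), centered Moreau-Broto
## autocorrelations weighted by intrinsic state (ATSCns), molecular walk
## counts (MWCnn) and the Labute approximate surface area (ASA).
## Definitions follow the published descriptor literature; Chi and ASA
## reproduce the rdkit reference implementation (fixtures frozen in the
## test suite).

.period_number <- function(Z) {
  findInterval(Z, c(1, 3, 11, 19, 37, 55))
}

## ---- path enumeration -------------------------------------------------

## All bond-trails with exactly `nb` distinct bonds (atoms may repeat,
## bonds may not).  Each undirected trail is counted once, identified
## by its bond set.  The returned atom sequence is the visit order; a
## final atom equal to the first (a closed ring) is dropped, so a pure
## cycle of `nb` bonds contributes each atom once while a ring-plus-tail
## trail keeps its revisited atom twice.  This matches the reference
## connectivity-index implementation on the fixture set.
.bond_paths <- function(g, nb) {
  bonds <- g$bonds
  n <- nrow(g$atoms)
  if (nb < 1L || nrow(bonds) < nb) return(list())
  adj <- vector("list", n)
  for (b in seq_len(nrow(bonds))) {
    i <- bonds$i[b]; j <- bonds$j[b]
    adj[[i]] <- rbind(adj[[i]], c(j, b))
    adj[[j]] <- rbind(adj[[j]], c(i, b))
  }
  seen <- new.env(hash = TRUE, parent = emptyenv())
  paths <- list()
  np <- 0L

  visit <- function(atom, path_atoms, path_bonds) {
    depth <- length(path_bonds)
    nbrs <- adj[[atom]]
    if (is.null(nbrs)) return()
    for (r in seq_len(nrow(nbrs))) {
      nxt <- nbrs[r, 1L]; bid <- nbrs[r, 2L]
      if (bid %in% path_bonds) next
      if (depth + 1L == nb) {
        key <- paste(sort(c(path_bonds, bid)), collapse = ".")
        if (is.null(seen[[key]])) {
          seen[[key]] <- TRUE
          np <<- np + 1L
          seq_atoms <- c(path_atoms, nxt)
          if (nxt == seq_atoms[1L]) {
            seq_atoms <- seq_atoms[-length(seq_atoms)]
          }
          paths[[np]] <<- seq_atoms
        }
      } else {
        visit(nxt, c(path_atoms, nxt), c(path_bonds, bid))
      }
    }
  }

  for (s in seq_len(n)) visit(s, s, integer())
  paths
}

## ---- individual descriptors ------------------------------------------

#' Valence-weighted Chi path index
#'
#' Kier-Hall connectivity index of path order `order`: the sum over all
#' simple bond-paths of `order` bonds of the product of 1/sqrt(delta_v)
#' over the atoms of the path (rings of `order` bonds count once, with
#' each atom entering the product once).  delta_v is the valence delta
#' (Zv - nH for second-row atoms, scaled by core size below).
#'
#' @param g a `mol_graph` from [parse_smiles()].
#' @param order path order (number of bonds, >= 1).
#' @return The Chi path index (0 when no such path exists).
#' @export
chi_path_v <- function(g, order) {
  stopifnot(inherits(g, "mol_graph"), order >= 1L)
  paths <- .bond_paths(g, as.integer(order))
  if (!length(paths)) return(0)
  dv <- g$atoms$delta_v
  w <- ifelse(dv > 0, 1 / sqrt(dv), 0)
  sum(vapply(paths, function(p) prod(w[p]), numeric(1)))
}

#' ETA core count (ETA_alpha)
#'
#' Extended Topochemical Atom core count: the sum over heavy atoms of
#' alpha_i = ((Z - Zv)/Z) / (PN - 1), where Z is the atomic number, Zv
#' the valence electron count and PN the period number.  Captures the
#' skeletal/electronic bulk of the molecular core (1/3 per sp3-row
#' carbon).
#'
#' @inheritParams chi_path_v
#' @return ETA_alpha.
#' @export
eta_alpha <- function(g) {
  stopifnot(inherits(g, "mol_graph"))
  Z <- .atomic_number[g$atoms$elem]
  Zv <- .n_outer[g$atoms$elem]
  pn <- .period_number(Z)
  sum(((Z - Zv) / Z) / (pn - 1))
}

#' Galvez mean topological charge index
#'
#' From the charge-transfer matrix CT = M - t(M) with M = A Dstar,
#' where A is the adjacency matrix and Dstar the inverse-square
#' topological distance matrix (zero diagonal): the charge index of
#' order k is G_k = sum over atom pairs at distance k of |CT_ij|, and
#' the mean index is JGI_k = G_k / (n - 1).
#'
#' @inheritParams chi_path_v
#' @param order topological distance k (>= 1).
#' @return JGI_k (0 for a single-atom graph).
#' @export
jgi <- function(g, order) {
  stopifnot(inherits(g, "mol_graph"), order >= 1L)
  n <- nrow(g$atoms)
  if (n < 2L) return(0)
  Dstar <- ifelse(is.finite(g$D) & g$D > 0, 1 / g$D^2, 0)
  M <- g$A %*% Dstar
  CT <- M - t(M)
  at_k <- g$D == order
  at_k[lower.tri(at_k, diag = TRUE)] <- FALSE
  sum(abs(CT[at_k])) / (n - 1)
}

#' Kier-Hall intrinsic state of each heavy atom
#'
#' I_i = ((2/PN)^2 delta_v + 1) / delta, with delta the heavy-atom
#' degree.  Undefined (NaN) for isolated atoms.
#'
#' @inheritParams chi_path_v
#' @return Numeric vector, one value per heavy atom.
#' @export
intrinsic_state <- function(g) {
  stopifnot(inherits(g, "mol_graph"))
  pn <- .period_number(.atomic_number[g$atoms$elem])
  ((2 / pn)^2 * g$atoms$delta_v + 1) / g$atoms$degree
}

#' Centered Moreau-Broto autocorrelation (intrinsic-state weighted)
#'
#' ATSC_k(s) = sum over unordered atom pairs at topological distance k
#' of (s_i - mean(s)) (s_j - mean(s)), with s the intrinsic state; for
#' k = 0 the sum of squared centered weights.  Captures how
#' electro-topological character is distributed across k-bond
#' neighborhoods.
#'
#' @inheritParams chi_path_v
#' @param order lag k (>= 0).
#' @return ATSC_k; 0 when no atom pair sits at distance k.
#' @export
atsc_s <- function(g, order) {
  stopifnot(inherits(g, "mol_graph"), order >= 0L)
  n <- nrow(g$atoms)
  if (order > 0L) {
    at_k <- is.finite(g$D) & g$D == order
    at_k[lower.tri(at_k, diag = TRUE)] <- FALSE
    if (!any(at_k)) return(0)
  }
  s <- intrinsic_state(g)
  if (any(!is.finite(s))) return(NA_real_)
  cs <- s - mean(s)
  if (order == 0L) return(sum(cs^2))
  sum(outer(cs, cs)[at_k])
}

#' Molecular walk count
#'
#' Total number of walks of length `order` in the hydrogen-suppressed
#' graph (the sum of all entries of the order-th power of the adjacency
#' matrix).  Returned log-scaled as ln(1 + count) by default: walk
#' counts grow combinatorially with size and cyclicity, and the
#' log-scaled form keeps the descriptor on the O(10) scale of the other
#' catalogue members.
#'
#' @inheritParams chi_path_v
#' @param order walk length (>= 1).
#' @param log_scale return ln(1 + count) (default) instead of the raw
#'   count.
#' @return The (possibly log-scaled) walk count.
#' @export
mwc <- function(g, order, log_scale = TRUE) {
  stopifnot(inherits(g, "mol_graph"), order >= 1L)
  Ak <- diag(nrow(g$A))
  for (k in seq_len(order)) Ak <- Ak %*% g$A
  count <- sum(Ak)
  if (log_scale) log1p(count) else count
}

#' Labute approximate surface area
#'
#' Approximate van-der-Waals surface area from sphere areas minus
#' pairwise cap overlaps at ideal bond lengths (Rb0 radii; bond-length
#' offsets 0.1/0/0.2/0.3 angstrom for aromatic/single/double/triple
#' bonds).  This is an exact port of the reference implementation,
#' including its treatment of hydrogens as a single shared sphere
#' interacting once with every heavy atom.
#'
#' @inheritParams chi_path_v
#' @return Approximate surface area in angstrom^2.
#' @export
labute_asa <- function(g) {
  stopifnot(inherits(g, "mol_graph"))
  n <- nrow(g$atoms)
  rads <- c(.rb0[g$atoms$elem], H = unname(.rb0["H"]))
  Vi <- numeric(n + 1L)
  scale_fact <- c(`1` = 0, `2` = 0.2, `3` = 0.3)

  bonds <- g$bonds
  if (nrow(bonds) > 0L) {
    for (b in seq_len(nrow(bonds))) {
      i <- bonds$i[b]; j <- bonds$j[b]
      Ri <- rads[i]; Rj <- rads[j]
      off <- if (isTRUE(bonds$aromatic[b])) 0.1 else
        scale_fact[[as.character(min(bonds$order[b], 3L))]]
      bij <- Ri + Rj - off
      dij <- min(max(abs(Ri - Rj), bij), Ri + Rj)
      Vi[i] <- Vi[i] + Rj^2 - (Ri - dij)^2 / dij
      Vi[j] <- Vi[j] + Ri^2 - (Rj - dij)^2 / dij
    }
  }
  ## shared hydrogen sphere: one interaction per heavy atom
  Rh <- rads[n + 1L]
  for (i in seq_len(n)) {
    Ri <- rads[i]
    dij <- Ri + Rh
    Vi[i] <- Vi[i] + Rh^2 - (Ri - dij)^2 / dij
    Vi[n + 1L] <- Vi[n + 1L] + Ri^2 - (Rh - dij)^2 / dij
  }
  areas <- 4 * pi * rads^2 - pi * rads * Vi
  sum(areas)
}

## ---- catalogue dispatch ----------------------------------------------

.descriptor_catalogue_patterns <- c(
  "^Xp([0-9])dv$", "^ETA_alpha$", "^JGI([0-9])$", "^ATSC([0-9])s$",
  "^MWC([0-9]{2})$", "^ASA$"
)

#' Names of the supported topological descriptors
#'
#' The catalogue covers the descriptor families used by the published
#' solubility model: `Xp0dv`..`Xp7dv`, `ETA_alpha`, `JGI1`..`JGI5`,
#' `ATSC0s`..`ATSC8s`, `MWC01`..`MWC10`, `ASA`.
#'
#' @return Character vector of descriptor names.
#' @export
descriptor_catalogue <- function() {
  c(paste0("Xp", 1:7, "dv"), "ETA_alpha", paste0("JGI", 1:5),
    paste0("ATSC", 0:8, "s"), sprintf("MWC%02d", 1:10), "ASA")
}

.compute_descriptor <- function(g, name, mwc_log = TRUE) {
  if (name == "ETA_alpha") return(eta_alpha(g))
  if (name == "ASA") return(labute_asa(g))
  m <- regmatches(name, regexec("^Xp([0-9])dv$", name))[[1]]
  if (length(m)) return(chi_path_v(g, as.integer(m[2])))
  m <- regmatches(name, regexec("^JGI([0-9])$", name))[[1]]
  if (length(m)) return(jgi(g, as.integer(m[2])))
  m <- regmatches(name, regexec("^ATSC([0-9])s$", name))[[1]]
  if (length(m)) return(atsc_s(g, as.integer(m[2])))
  m <- regmatches(name, regexec("^MWC([0-9]{2})$", name))[[1]]
  if (length(m)) return(mwc(g, as.integer(m[2]), log_scale = mwc_log))
  stop("unknown descriptor name: '", name, "'", call. = FALSE)
}

#' Compute topological descriptors for a compound table
#'
#' Evaluates the requested catalogue descriptors for each compound's
#' SMILES and returns a [feature_matrix()].  Molecules that fail to
#' parse are recorded as missing and surfaced through the
#' `"failures"` attribute (and a warning) so they can be handled before
#' preprocessing; unknown descriptor names are a configuration error.
#'
#' @param compounds a compound table from [read_compound_table()] (or
#'   any data.frame with `id` and `smiles` columns, optionally `logS`).
#' @param descriptor_set descriptor names drawn from
#'   [descriptor_catalogue()].
#' @param mwc_log use the log-scaled walk count (default; see [mwc()]).
#' @return A `feature_matrix` whose columns are the requested
#'   descriptors (provenance `"topological"`), with the compound `logS`
#'   as target when present.  Attribute `"failures"` maps compound ids
#'   to failure messages; attribute `"catalogue_version"` records the
#'   catalogue identity (including the active walk-count scaling).
#' @export
compute_topological_descriptors <- function(compounds,
                                            descriptor_set = published_descriptor_names(),
                                            mwc_log = TRUE) {
  stopifnot(is.data.frame(compounds),
            all(c("id", "smiles") %in% names(compounds)))
  unknown <- setdiff(descriptor_set, descriptor_catalogue())
  if (length(unknown)) {
    stop("unknown descriptor name(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  n <- nrow(compounds)
  X <- matrix(NA_real_, n, length(descriptor_set),
              dimnames = list(compounds$id, descriptor_set))
  failures <- character()
  for (r in seq_len(n)) {
    g <- tryCatch(parse_smiles(compounds$smiles[r])[[1L]],
                  error = function(e) conditionMessage(e))
    if (!inherits(g, "mol_graph")) {
      failures[compounds$id[r]] <- g
      next
    }
    X[r, ] <- vapply(descriptor_set, function(nm)
      .compute_descriptor(g, nm, mwc_log = mwc_log), numeric(1))
  }
  if (length(failures)) {
    warning("descriptor computation failed for ", length(failures),
            " compound(s): ", paste(names(failures), collapse = ", "),
            call. = FALSE)
  }
  fm <- feature_matrix(X, row_ids = compounds$id,
                       target = if ("logS" %in% names(compounds))
                         compounds$logS else NULL,
                       provenance = rep("topological", ncol(X)))
  attr(fm, "failures") <- failures
  attr(fm, "catalogue_version") <- paste0(
    "oemsol-native-1 (mwc ", if (mwc_log) "log" else "raw", ")")
  fm
}

#' Descriptor names appearing in the published symbolic model
#' @return Character vector of the eight topological names.
#' @export
published_descriptor_names <- function() {
  c("Xp4dv", "Xp6dv", "Xp7dv", "ETA_alpha", "JGI2", "ASA", "ATSC3s", "MWC07")
}
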