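## Sparse symbolic regression over descriptor spaces.
##
## The discovery pipeline screens primary descriptors by mutual
## information with logS, recursively combines the survivors with a
## restricted operator library into a structured candidate space,
## filters candidates by marginal correlation (sure independence
## screening), and selects a sparse additive model by exhaustive
## l0-penalized best-subset least squares.  Every stage is deterministic
## given the seed, with ties broken by (lower complexity, then
## lexicographic canonical string).

## ---- mutual information ----------------------------------------------

#' k-nearest-neighbor mutual information estimate
#'
#' Kraskov-Stoegbauer-Grassberger estimator (variant 1) for two
#' continuous variables, using the max-norm in the joint space:
#' MI = digamma(k) + digamma(n) - mean(digamma(nx+1) + digamma(ny+1)).
#' Suited to the few-dozen-sample regime; estimates can be slightly
#' negative for independent variables.
#'
#' @param x,y numeric vectors of equal length.
#' @param k neighbor count (default 3).
#' @return Estimated mutual information in nats.
#' @export
mi_knn <- function(x, y, k = 3L) {
  n <- length(x)
  stopifnot(length(y) == n, n > k + 1L)
  dx <- abs(outer(x, x, "-"))
  dy <- abs(outer(y, y, "-"))
  dz <- pmax(dx, dy)
  diag(dz) <- Inf
  eps <- apply(dz, 1L, function(r) sort(r, partial = k)[k])
  nx <- rowSums(dx < eps) - 1L
  ny <- rowSums(dy < eps) - 1L
  digamma(k) + digamma(n) - mean(digamma(nx + 1L) + digamma(ny + 1L))
}

#' Binned (plug-in) mutual information estimate
#'
#' Equal-frequency binning of both variables followed by the plug-in
#' estimate on the contingency table.
#'
#' @param x,y numeric vectors of equal length.
#' @param bins number of quantile bins per variable.
#' @return Estimated mutual information in nats.
#' @export
mi_binned <- function(x, y, bins = 8L) {
  cutq <- function(v) {
    br <- unique(stats::quantile(v, probs = seq(0, 1, length.out = bins + 1)))
    if (length(br) < 2L) return(rep(1L, length(v)))
    as.integer(cut(v, br, include.lowest = TRUE))
  }
  tab <- table(cutq(x), cutq(y))
  p <- tab / sum(tab)
  px <- rowSums(p); py <- colSums(p)
  nz <- p > 0
  sum(p[nz] * log(p[nz] / outer(px, py)[nz]))
}

#' Rank descriptors by mutual information with the target
#'
#' @param fm a `feature_matrix` with target.
#' @param k how many top-ranked descriptor names to return (>= 1).
#' @param estimator `"knn"` (default, k-nearest-neighbor) or
#'   `"binning"` (equal-frequency bins).
#' @param knn_k,bins estimator tuning constants.
#' @return Character vector of the top-k descriptor names, ranked by
#'   decreasing estimated MI (ties broken by column name).
#' @export
mi_screen <- function(fm, k, estimator = c("knn", "binning"),
                      knn_k = 3L, bins = 8L) {
  stopifnot(inherits(fm, "feature_matrix"), !is.null(fm$target))
  estimator <- match.arg(estimator)
  if (k <= 0) stop("config error: k must be >= 1", call. = FALSE)
  if (k > ncol(fm$X)) stop("config error: k exceeds the number of columns",
                           call. = FALSE)
  y <- fm$target
  mi <- vapply(seq_len(ncol(fm$X)), function(j) {
    if (estimator == "knn") mi_knn(fm$X[, j], y, k = knn_k)
    else mi_binned(fm$X[, j], y, bins = bins)
  }, numeric(1))
  nm <- colnames(fm$X)
  nm[order(-mi, nm)][seq_len(k)]
}

## ---- candidate expansion ----------------------------------------------

#' Expand screened descriptors into a candidate expression space
#'
#' Recursively combines the selected primary descriptors with the
#' operator library for `depth` rounds; each round squares the newest
#' expressions and combines them (pairwise) with everything generated so
#' far.  Duplicates are removed by canonical form (commutative operands
#' sorted, associative chains flattened); candidates with any non-finite
#' value (division blow-ups) or (near-)constant value are dropped and
#' logged.
#'
#' @param selected primary descriptor names (from [mi_screen()]).
#' @param fm the `feature_matrix` holding their columns and the target.
#' @param operators subset of `c("+", "-", "*", "/", "^2")`.
#' @param depth number of composition rounds (>= 1).
#' @param cap maximum candidate count; exceeding it is an error asking
#'   for a lower depth / fewer screened descriptors.
#' @return A `candidate_set`: list with `M` (n x m value matrix),
#'   `strs` (canonical strings; trees are materialized on demand with
#'   [parse_expression()]), `complexity`, `target`, and `dropped`
#'   (data.frame of dropped canonical forms with reasons).
#' @export
expand_features <- function(selected, fm,
                            operators = c("+", "-", "*", "/", "^2"),
                            depth = 2L, cap = 50000L) {
  stopifnot(inherits(fm, "feature_matrix"),
            all(selected %in% colnames(fm$X)), depth >= 1L)
  bad <- setdiff(operators, c("+", "-", "*", "/", "^2"))
  if (length(bad)) stop("unsupported operator(s): ",
                        paste(bad, collapse = ", "), call. = FALSE)

  n <- nrow(fm$X)
  strs <- selected
  cplx <- rep(1L, length(selected))
  round_born <- rep(0L, length(selected))
  cols <- lapply(selected, function(nm) fm$X[, nm])
  ## top-level argument strings for n-ary roots, used to flatten and
  ## sort commutative chains without building trees
  targ <- lapply(selected, function(s) NULL)
  root <- rep(NA_character_, length(selected))
  seen <- new.env(hash = TRUE, parent = emptyenv())
  for (s in strs) assign(s, TRUE, envir = seen)
  dropped <- list()

  ok_value <- function(v) {
    if (any(!is.finite(v))) return("non-finite")
    if (stats::sd(v) <= 1e-10 * (1 + abs(mean(v)))) return("constant")
    NULL
  }
  top_args <- function(i, op) {
    if (identical(root[[i]], op)) targ[[i]] else strs[[i]]
  }
  add <- function(s, v, born, cx, op = NA_character_, args = NULL) {
    if (!is.null(seen[[s]])) return()
    assign(s, TRUE, envir = seen)
    why <- ok_value(v)
    if (!is.null(why)) {
      dropped[[length(dropped) + 1L]] <<- c(s, why)
      return()
    }
    m <- length(strs) + 1L
    if (m > cap) {
      stop("candidate cap (", cap, ") exceeded; lower the expansion ",
           "depth or the number of screened descriptors", call. = FALSE)
    }
    strs[m] <<- s
    cplx[m] <<- cx
    round_born[m] <<- born
    cols[[m]] <<- v
    root[m] <<- op
    targ[[m]] <<- args
  }

  for (r in seq_len(depth)) {
    prev_n <- length(strs)
    new_idx <- which(round_born == r - 1L)
    old_idx <- seq_len(prev_n)
    if ("^2" %in% operators) {
      for (i in new_idx) {
        add(paste0("(^2 ", strs[[i]], ")"), cols[[i]]^2, r, cplx[[i]] + 1L)
      }
    }
    binops <- intersect(operators, c("+", "-", "*", "/"))
    if (length(binops)) {
      for (i in new_idx) {
        for (j in old_idx) {
          if (j == i) next
          ## each unordered pair once, with at least one member new
          if (j > i && round_born[j] == r - 1L) next
          vi <- cols[[i]]; vj <- cols[[j]]
          cx <- cplx[[i]] + cplx[[j]] + 1L
          for (op in binops) {
            if (op %in% c("+", "*")) {
              args <- sort(c(top_args(i, op), top_args(j, op)),
                           method = "radix")
              s <- paste0("(", op, " ", paste(args, collapse = " "), ")")
              add(s, if (op == "+") vi + vj else vi * vj, r, cx, op, args)
            } else {
              add(paste0("(", op, " ", strs[[i]], " ", strs[[j]], ")"),
                  if (op == "-") vi - vj else vi / vj, r, cx)
              add(paste0("(", op, " ", strs[[j]], " ", strs[[i]], ")"),
                  if (op == "-") vj - vi else vj / vi, r, cx)
            }
          }
        }
      }
    }
  }

  M <- do.call(cbind, cols)
  colnames(M) <- strs
  structure(list(
    M = M, strs = strs, complexity = cplx,
    target = fm$target, row_ids = fm$row_ids,
    unit_system = fm$unit_system,
    dropped = if (length(dropped)) {
      d <- do.call(rbind, dropped)
      data.frame(candidate = d[, 1L], reason = d[, 2L])
    } else data.frame(candidate = character(), reason = character())
  ), class = "candidate_set")
}

#' @export
print.candidate_set <- function(x, ...) {
  cat(sprintf("candidate_set: %d expressions x %d rows (%d dropped)\n",
              length(x$strs), nrow(x$M), nrow(x$dropped)))
  invisible(x)
}

.candidate_subset <- function(cs, idx) {
  structure(list(M = cs$M[, idx, drop = FALSE],
                 strs = cs$strs[idx], complexity = cs$complexity[idx],
                 target = cs$target, row_ids = cs$row_ids,
                 unit_system = cs$unit_system, dropped = cs$dropped),
            class = "candidate_set")
}

#' Sure independence screening of candidate expressions
#'
#' Retains the `m` candidates with the largest absolute Pearson
#' correlation with the target, computed after standardizing candidate
#' columns on the rows present (training rows only, when called inside
#' cross-validation).  Ties are broken by lower complexity, then
#' lexicographic canonical string.
#'
#' @param candidates a `candidate_set` with target.
#' @param m number of candidates to keep (<= candidate count).
#' @return The reduced `candidate_set`.
#' @export
sis_filter <- function(candidates, m) {
  stopifnot(inherits(candidates, "candidate_set"),
            !is.null(candidates$target))
  k <- length(candidates$strs)
  if (m > k) stop("m exceeds the candidate count", call. = FALSE)
  sds <- apply(candidates$M, 2L, stats::sd)
  usable <- which(sds > 0)
  r <- abs(suppressWarnings(
    stats::cor(candidates$M[, usable, drop = FALSE], candidates$target)))
  r[!is.finite(r)] <- 0
  ord <- usable[order(-r, candidates$complexity[usable],
                      candidates$strs[usable])]
  .candidate_subset(candidates, ord[seq_len(min(m, length(ord)))])
}

## ---- sparse model ------------------------------------------------------

#' Construct a sparse symbolic model
#'
#' @param terms list of `list(coefficient =, expression =)` pairs.
#' @param intercept numeric intercept.
#' @param r_squared,rmse training metrics.
#' @param config named list snapshot of the stage configuration
#'   (operators, depth, SIS size, penalty, seed, ...).
#' @param unit_system unit tag.
#' @param data_checksum small checksum of the training data (n, sum of
#'   candidate values, sum of target) so reported metrics can be tied to
#'   the data they were computed on.
#' @return An object of class `symbolic_model`.
#' @export
symbolic_model <- function(terms, intercept, r_squared = NA_real_,
                           rmse = NA_real_, config = list(),
                           unit_system = "kJ", data_checksum = NULL) {
  stopifnot(is.list(terms))
  for (t in terms) {
    stopifnot(is.finite(t$coefficient), inherits(t$expression, "sr_expression"))
  }
  stopifnot(is.finite(intercept))
  structure(list(terms = terms, intercept = intercept,
                 r_squared = r_squared, rmse = rmse, config = config,
                 unit_system = check_unit_system(unit_system),
                 data_checksum = data_checksum),
            class = "symbolic_model")
}

#' @export
print.symbolic_model <- function(x, ...) {
  cat("symbolic model [", x$unit_system, "]:\n", sep = "")
  cat("  logS =", format(x$intercept, digits = 6))
  for (t in x$terms) {
    cat(sprintf(" %s %s * %s",
                if (t$coefficient < 0) "-" else "+",
                format(abs(t$coefficient), digits = 6),
                format_expression(t$expression)))
  }
  cat("\n")
  if (is.finite(x$r_squared)) {
    cat(sprintf("  training R^2 = %.4f, RMSE = %.4f\n", x$r_squared, x$rmse))
  }
  invisible(x)
}

#' Canonical strings of a model's terms
#' @param model a `symbolic_model`.
#' @return Character vector (sorted) of term canonical forms.
#' @export
model_support <- function(model) {
  sort(vapply(model$terms, function(t) format_expression(t$expression),
              character(1)))
}

#' Exhaustive l0-regularized best-subset regression
#'
#' Searches all supports of size 0..`max_support` over the candidate
#' columns; fits each by ordinary least squares (with intercept) and
#' selects the support minimizing MSE + penalty * support size.
#' Singular supports are skipped; ties are broken by lower total
#' complexity, then lexicographic concatenated canonical string.
#'
#' @param candidates a `candidate_set` (typically the SIS survivors).
#' @param max_support largest support size, at most `min(8, m)`.
#' @param penalty l0 penalty per selected term (in squared-logS units).
#' @param config extra configuration recorded in the model.
#' @return A fitted `symbolic_model`.
#' @export
l0_regress <- function(candidates, max_support = 3L, penalty = 0,
                       config = list()) {
  stopifnot(inherits(candidates, "candidate_set"))
  m <- length(candidates$strs)
  y <- candidates$target
  n <- length(y)
  if (max_support > min(8L, m)) {
    stop("max_support must be <= min(8, candidate count)", call. = FALSE)
  }
  if (n <= max_support + 1L) {
    stop("need n > max_support + 1 rows", call. = FALSE)
  }
  X1 <- cbind(`(intercept)` = 1, candidates$M)
  G <- crossprod(X1)
  Gy <- as.numeric(crossprod(X1, y))
  yty <- sum(y * y)

  per_size <- .best_subsets_cpp(G, Gy, yty, as.integer(max_support))

  ## penalized objective across sizes; deterministic tie-breaking by
  ## (total complexity, lexicographic canonical key) among exact ties
  best <- NULL
  for (s in seq_along(per_size)) {
    entry <- per_size[[s]]
    if (!is.finite(entry$rss)) next
    obj <- entry$rss / n + penalty * (s - 1L)
    for (support in entry$supports) {
      support <- as.integer(support)
      tot_cplx <- if (length(support)) {
        sum(candidates$complexity[support])
      } else 0L
      key <- paste(sort(candidates$strs[support]), collapse = " | ")
      if (is.null(best) || obj < best$obj - 1e-12 ||
          (abs(obj - best$obj) <= 1e-12 &&
           (tot_cplx < best$cplx ||
            (tot_cplx == best$cplx && key < best$key)))) {
        best <- list(obj = obj, mse = entry$rss / n, support = support,
                     cplx = tot_cplx, key = key)
      }
    }
  }

  support <- best$support
  sub <- c(1L, support + 1L)
  b <- solve(G[sub, sub, drop = FALSE], Gy[sub])
  terms <- lapply(seq_along(support), function(i)
    list(coefficient = unname(b[i + 1L]),
         expression = parse_expression(candidates$strs[support[i]])))
  fitted <- as.numeric(X1[, c(1L, support + 1L), drop = FALSE] %*% b)
  symbolic_model(
    terms = terms, intercept = unname(b[1L]),
    r_squared = if (stats::var(y) > 0) r2(y, fitted) else 0,
    rmse = rmse(y, fitted),
    config = c(config, list(penalty = penalty, max_support = max_support,
                            objective = best$obj)),
    unit_system = candidates$unit_system,
    data_checksum = c(n = n, sum_x = sum(candidates$M), sum_y = sum(y)))
}

## ---- discovery pipeline ------------------------------------------------

#' Default configuration of the discovery pipeline
#'
#' @param mi_k primary descriptors kept by MI screening.
#' @param mi_estimator `"knn"` or `"binning"`.
#' @param operators operator library.
#' @param depth expansion depth.
#' @param sis_size candidates kept by sure independence screening.
#' @param max_support largest model support searched exhaustively.
#' @param penalty_grid l0 penalties swept; the per-penalty winners are
#'   compared by BIC.
#' @param cap candidate-count cap for the expansion.
#' @param var_eps preprocessing variance threshold.
#' @return Named list of stage parameters.
#' @export
discover_config <- function(mi_k = 6L, mi_estimator = "knn",
                            operators = c("+", "-", "*", "/", "^2"),
                            depth = 2L, sis_size = 500L, max_support = 3L,
                            penalty_grid = c(0, 1e-4, 1e-3, 1e-2),
                            cap = 50000L, var_eps = 0) {
  list(mi_k = mi_k, mi_estimator = mi_estimator, operators = operators,
       depth = depth, sis_size = sis_size, max_support = max_support,
       penalty_grid = penalty_grid, cap = cap, var_eps = var_eps)
}

## Screened exhaustive search.  The candidate pool is the union of the
## top-`sis_size` candidates by marginal correlation with the target
## (sure independence screening) and smaller batches screened against
## the residuals of the best lower-dimensional models (the iterative
## screening scheme of the SIS + l0 family: later terms are only
## visible in the residual once the dominant ones are accounted for).
## The best support per size is then found by an exhaustive subset
## search over the pooled candidates.  Returns the best model per size
## (after deterministic tie-breaking) as lists (mse, support).
.staged_best_by_size <- function(cands, sis_size, max_support,
                                 residual_batch = 50L) {
  y <- cands$target
  n <- length(y)
  X1 <- cbind(1, cands$M)
  yty <- sum(y * y)
  sds <- apply(cands$M, 2L, stats::sd)

  screen_top <- function(resid, k, exclude = integer(0)) {
    r <- abs(suppressWarnings(stats::cor(cands$M, resid)))
    r[!is.finite(r)] <- 0
    r[sds <= 0] <- -Inf
    ord <- order(-r, cands$complexity, cands$strs)
    utils::head(setdiff(ord, exclude), k)
  }

  ## complexity-stratified marginal screening: most of the budget goes
  ## to shallow candidates (complexity <= 5: primaries, single-operator
  ## combinations and their products with a primary), where the
  ## parsimony objective expects the selected terms to live; deep
  ## candidates crowd a flat correlation ranking because every
  ## high-order recombination of relevant primaries correlates with the
  ## target
  screen_marginal <- function(k) {
    shallow <- which(cands$complexity <= 5L)
    k_shallow <- min(length(shallow), ceiling(0.7 * k))
    r <- abs(suppressWarnings(stats::cor(cands$M, y)))
    r[!is.finite(r)] <- 0
    r[sds <= 0] <- -Inf
    ord_all <- order(-r, cands$complexity, cands$strs)
    rs <- r[shallow]
    ord_sh <- shallow[order(-rs, cands$complexity[shallow],
                            cands$strs[shallow])]
    union(ord_sh[seq_len(k_shallow)],
          utils::head(ord_all, k - k_shallow))
  }

  tie_break <- function(entry) {
    best <- NULL
    for (support in entry$supports) {
      support <- as.integer(support)
      cplx <- if (length(support)) sum(cands$complexity[support]) else 0L
      key <- paste(sort(cands$strs[support]), collapse = " | ")
      if (is.null(best) || cplx < best$cplx ||
          (cplx == best$cplx && key < best$key)) {
        best <- list(support = support, cplx = cplx, key = key)
      }
    }
    best
  }

  by_size <- vector("list", max_support + 1L)
  by_size[[1L]] <- list(mse = mean((y - mean(y))^2), support = integer(0))

  run_exhaustive <- function(pool) {
    Xp <- X1[, c(1L, pool + 1L), drop = FALSE]
    Gp <- crossprod(Xp)
    Gyp <- as.numeric(crossprod(Xp, y))
    per_size <- .best_subsets_cpp(Gp, Gyp, yty, max_support)
    for (s in seq_len(max_support) + 1L) {
      entry <- per_size[[s]]
      if (!is.finite(entry$rss)) next
      entry$supports <- lapply(entry$supports,
                               function(ix) pool[as.integer(ix)])
      mse <- entry$rss / n
      if (is.null(by_size[[s]]) || mse < by_size[[s]]$mse - 1e-12) {
        bb <- tie_break(entry)
        by_size[[s]] <<- list(mse = mse, support = bb$support)
      }
    }
  }

  ## residual batches from a quick greedy pass
  pool <- screen_top(y - mean(y), residual_batch)
  resid <- y - mean(y)
  for (d in seq_len(max_support)) {
    Xp <- X1[, c(1L, pool + 1L), drop = FALSE]
    Gp <- crossprod(Xp)
    Gyp <- as.numeric(crossprod(Xp, y))
    per <- .best_subsets_cpp(Gp, Gyp, yty, d)
    entry <- per[[d + 1L]]
    if (is.finite(entry$rss) && length(entry$supports)) {
      sup <- pool[as.integer(entry$supports[[1L]])]
      Xd <- X1[, c(1L, sup + 1L), drop = FALSE]
      resid <- as.numeric(qr.resid(qr(Xd), y))
    }
    if (d < max_support) {
      pool <- sort(union(pool, screen_top(resid, residual_batch, pool)))
    }
  }

  ## final pool: stratified marginal screening + the residual batches
  pool <- sort(union(screen_marginal(sis_size), pool))
  run_exhaustive(pool)

  ## conditional re-screening: anchor each selected term in turn,
  ## screen the dictionary against the residual of the anchored fit,
  ## and re-run the exhaustive search over the anchored elite.  A
  ## partially correct model leaves the missing terms exposed in its
  ## single-term residuals even when the full-model residual hides
  ## them.
  for (iter in 1:2) {
    bs <- by_size[[max_support + 1L]]
    if (is.null(bs) || !length(bs$support)) break
    prev <- bs$support
    for (t in seq_along(prev)) {
      Xa <- X1[, c(1L, prev[t] + 1L), drop = FALSE]
      resid_a <- as.numeric(qr.resid(qr(Xa), y))
      elite <- screen_top(resid_a, 250L, exclude = prev)
      run_exhaustive(sort(union(prev, elite)))
    }
    if (identical(by_size[[max_support + 1L]]$support, prev)) break
  }
  list(by_size = by_size, X1 = X1)
}

## Local combinatorial refinement of a support: repeatedly tries to
## swap each selected column against every candidate (best-subset
## coordinate descent).  For each position the other columns are
## projected out and the replacement maximizing the residual-sum-of-
## squares reduction is taken; sweeps continue until no swap improves
## the fit.  Deterministic: ties go to lower complexity, then
## lexicographic canonical string.
.refine_support <- function(cands, support, max_sweeps = 20L) {
  if (!length(support)) return(support)
  M <- cands$M
  y <- cands$target
  n <- length(y)
  cplx <- cands$complexity
  strs <- cands$strs
  col_norm2 <- colSums(M^2)
  for (sweep in seq_len(max_sweeps)) {
    changed <- FALSE
    for (t in seq_along(support)) {
      others <- support[-t]
      Q <- qr.Q(qr(cbind(1, M[, others, drop = FALSE])))
      yt <- y - Q %*% crossprod(Q, y)
      Mt <- M - Q %*% crossprod(Q, M)
      nrm <- colSums(Mt^2)
      score <- as.numeric(crossprod(Mt, yt))^2 / pmax(nrm, 1e-300)
      ## exclude candidates collinear with the kept columns
      score[nrm <= 1e-10 * (col_norm2 + 1e-300)] <- -Inf
      score[others] <- -Inf
      cur <- support[t]
      best <- order(-score, cplx, strs)[1L]
      if (score[best] > score[cur] * (1 + 1e-10) + 1e-12 && best != cur) {
        support[t] <- best
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  sort(support)
}

.model_from_support <- function(cands, search, support, config = list()) {
  y <- cands$target
  n <- length(y)
  sub <- c(1L, support + 1L)
  Xs <- search$X1[, sub, drop = FALSE]
  b <- qr.coef(qr(Xs), y)
  fitted <- as.numeric(Xs %*% b)
  terms <- lapply(seq_along(support), function(i)
    list(coefficient = unname(b[i + 1L]),
         expression = parse_expression(cands$strs[support[i]])))
  symbolic_model(
    terms = terms, intercept = unname(b[1L]),
    r_squared = if (stats::var(y) > 0) r2(y, fitted) else 0,
    rmse = rmse(y, fitted), config = config,
    unit_system = cands$unit_system,
    data_checksum = c(n = n, sum_x = sum(cands$M), sum_y = sum(y)))
}

#' Discover a sparse symbolic solubility model
#'
#' Composes the pipeline stages: variance-filter preprocessing, MI
#' screening of primary descriptors, operator expansion, and a sequence
#' of l0-regularized best-subset steps with sure-independence screening
#' applied in residual batches (each support size screens a fresh batch
#' of candidates against the current residual before the exhaustive
#' subset search).  The per-penalty winners across the grid are
#' compared by BIC.  The full configuration and seed are stored in the
#' returned model; two runs with the same seed and config are
#' identical.
#'
#' @param fm a `feature_matrix` with target (training rows only).
#' @param config a [discover_config()] list.
#' @param seed integer seed.
#' @return A fitted `symbolic_model`.
#' @export
discover <- function(fm, config = discover_config(), seed = 1L) {
  stopifnot(inherits(fm, "feature_matrix"), !is.null(fm$target))
  set.seed(seed)
  pre <- preprocess_design_matrix(fm, var_eps = config$var_eps)
  k <- min(config$mi_k, ncol(pre$X))
  sel <- mi_screen(pre, k = k, estimator = config$mi_estimator)
  cands <- expand_features(sel, pre, operators = config$operators,
                           depth = config$depth, cap = config$cap)
  search <- .staged_best_by_size(cands, sis_size = config$sis_size,
                                 max_support = config$max_support)
  n <- length(cands$target)
  ## local combinatorial refinement of each support size against the
  ## full candidate space
  for (s in seq_along(search$by_size)) {
    bs <- search$by_size[[s]]
    if (is.null(bs) || !length(bs$support)) next
    ref <- .refine_support(cands, bs$support)
    Xr <- search$X1[, c(1L, ref + 1L), drop = FALSE]
    mse <- mean(qr.resid(qr(Xr), cands$target)^2)
    if (mse < bs$mse - 1e-12) {
      search$by_size[[s]] <- list(mse = mse, support = ref)
    }
  }

  ## per penalty: best size by penalized MSE; across penalties: BIC
  pick <- function(lam) {
    objs <- vapply(seq_along(search$by_size), function(s) {
      bs <- search$by_size[[s]]
      if (is.null(bs)) Inf else bs$mse + lam * (s - 1L)
    }, numeric(1))
    which.min(objs)
  }
  sizes <- vapply(config$penalty_grid, pick, integer(1))
  bic <- vapply(sizes, function(s) {
    n * log(search$by_size[[s]]$mse + 1e-300) + (s - 1L) * log(n)
  }, numeric(1))
  best_i <- which.min(bic)
  bs <- search$by_size[[sizes[best_i]]]
  .model_from_support(cands, search, bs$support,
                      config = c(config,
                                 list(seed = seed,
                                      penalty = config$penalty_grid[best_i],
                                      screened = sel)))
}

#' Evaluate a symbolic model on a feature matrix
#'
#' Termwise evaluation of the stored expressions on the descriptor
#' columns; any non-finite intermediate is an error naming the term and
#' the first offending row.
#'
#' @param model a `symbolic_model`.
#' @param fm a `feature_matrix` (or plain matrix/data.frame) holding
#'   every descriptor the model references.
#' @return Numeric vector of predicted logS, one per row.
#' @export
evaluate <- function(model, fm) {
  stopifnot(inherits(model, "symbolic_model"))
  data <- if (inherits(fm, "feature_matrix")) fm$X else fm
  need <- unique(unlist(lapply(model$terms,
                               function(t) expression_vars(t$expression))))
  missing_cols <- setdiff(need, colnames(data))
  if (length(missing_cols)) {
    stop("schema error: missing descriptor column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  pred <- rep(model$intercept, nrow(data))
  for (t in model$terms) {
    v <- eval_expression(t$expression, data)
    if (any(!is.finite(v))) {
      stop("non-finite value in term ", format_expression(t$expression),
           " at row ", which(!is.finite(v))[1L], call. = FALSE)
    }
    pred <- pred + t$coefficient * v
  }
  pred
}

#' Re-estimate a model's coefficients with the structure held fixed
#'
#' The term expressions are kept; coefficients and intercept are refit
#' by ordinary least squares on the supplied data (the fixed-structure
#' cross-validation primitive).
#'
#' @param model a `symbolic_model`.
#' @param fm a `feature_matrix` with target.
#' @return The refitted `symbolic_model` (same expressions, new
#'   coefficients and training metrics).
#' @export
refit_structure <- function(model, fm) {
  stopifnot(inherits(model, "symbolic_model"),
            inherits(fm, "feature_matrix"), !is.null(fm$target))
  y <- fm$target
  TM <- vapply(model$terms,
               function(t) eval_expression(t$expression, fm$X),
               numeric(nrow(fm$X)))
  TM <- matrix(TM, nrow = nrow(fm$X))
  X1 <- cbind(1, TM)
  qr_x <- qr(X1)
  if (qr_x$rank < ncol(X1)) {
    dep <- setdiff(seq_len(ncol(X1)), qr_x$pivot[seq_len(qr_x$rank)]) - 1L
    dep <- dep[dep > 0]
    stop("rank-deficient refit; collinear term(s): ",
         paste(vapply(model$terms[dep],
                      function(t) format_expression(t$expression),
                      character(1)), collapse = ", "), call. = FALSE)
  }
  b <- qr.coef(qr_x, y)
  fitted <- as.numeric(X1 %*% b)
  out <- model
  out$intercept <- unname(b[1L])
  for (i in seq_along(out$terms)) {
    out$terms[[i]]$coefficient <- unname(b[i + 1L])
  }
  out$r_squared <- if (stats::var(y) > 0) r2(y, fitted) else 0
  out$rmse <- rmse(y, fitted)
  out$data_checksum <- c(n = length(y), sum_x = sum(TM), sum_y = sum(y))
  out
}

## ---- published model ---------------------------------------------------

#' The published sparse symbolic solubility model
#'
#' Three product terms over thermodynamic (dG_solv, dH_sub) and
#' topological descriptors plus an intercept, with the published
#' coefficients (0.3014, -0.004736, -0.04027; intercept 1.55106), in
#' kJ/mol units.  The flattened published typography is ambiguous
#' between products and fractions; the default reading takes each term
#' as a pure product of its printed factors, and
#' `interpretation = "fraction"` instead treats each term's trailing
#' factor as a denominator.  The active interpretation and walk-count
#' scaling are recorded in the model's config.
#'
#' @param interpretation `"product"` (default) or `"fraction"`.
#' @param mwc_log whether the walk-count descriptor is the log-scaled
#'   form (recorded in the config; must match how the feature matrix
#'   was computed).
#' @return A `symbolic_model`.
#' @export
published_solubility_model <- function(interpretation = c("product", "fraction"),
                                       mwc_log = TRUE) {
  interpretation <- match.arg(interpretation)
  f1 <- list(ex_var("dG_solv"), ex_op("-", "Xp4dv", "Xp6dv"),
             ex_var("ETA_alpha"))
  f2 <- list(ex_var("Xp7dv"), ex_op("-", "dH_sub", "ASA"), ex_var("JGI2"))
  f3 <- list(ex_var("MWC07"), ex_var("Xp6dv"),
             ex_op("-", "ETA_alpha", "ATSC3s"))
  build <- function(fs) {
    if (interpretation == "product") {
      ex_op("*", fs[[1]], fs[[2]], fs[[3]])
    } else {
      ex_op("/", ex_op("*", fs[[1]], fs[[2]]), fs[[3]])
    }
  }
  symbolic_model(
    terms = list(
      list(coefficient = 0.3014,    expression = build(f1)),
      list(coefficient = -0.004736, expression = build(f2)),
      list(coefficient = -0.04027,  expression = build(f3))),
    intercept = 1.55106,
    config = list(source = "published", interpretation = interpretation,
                  mwc = if (mwc_log) "log" else "raw"),
    unit_system = "kJ")
}

## ---- serialization -----------------------------------------------------

#' Serialize a symbolic model to JSON
#'
#' Terms are stored as canonical prefix strings with their coefficients,
#' together with the intercept, metrics, config snapshot and unit tag.
#'
#' @param model a `symbolic_model`.
#' @param path optional output file; when `NULL` the JSON text is
#'   returned.
#' @return The JSON string (invisibly when written to `path`).
#' @export
write_symbolic_model <- function(model, path = NULL) {
  obj <- list(
    terms = lapply(model$terms, function(t)
      list(coefficient = t$coefficient,
           expression = format_expression(t$expression))),
    intercept = model$intercept, r_squared = model$r_squared,
    rmse = model$rmse, config = model$config,
    unit_system = model$unit_system, data_checksum = model$data_checksum)
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, null = "null")
  if (is.null(path)) return(as.character(js))
  writeLines(js, path)
  invisible(as.character(js))
}

#' Read a symbolic model from JSON
#' @param path file path (or a JSON string).
#' @return A `symbolic_model`.
#' @export
read_symbolic_model <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  symbolic_model(
    terms = lapply(obj$terms, function(t)
      list(coefficient = t$coefficient,
           expression = parse_expression(t$expression))),
    intercept = obj$intercept,
    r_squared = obj$r_squared %||% NA_real_,
    rmse = obj$rmse %||% NA_real_,
    config = obj$config %||% list(),
    unit_system = obj$unit_system %||% "kJ",
    data_checksum = unlist(obj$data_checksum))
}
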