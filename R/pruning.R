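#' Spearman correlation matrix of measures
#'
#' Pairwise Spearman rank correlations (average-rank tie handling, the
#' `stats::cor` default) across the pooled cohort.  For an
#' `imputed_ensemble` the matrix is the element-wise mean over the
#' completed datasets.
#'
#' @param x a complete `measure_table` or an `imputed_ensemble`.
#' @param ids measures to include (default: all).
#' @return A list of class `correlation_matrix` with `measure_ids` and
#'   the symmetric unit-diagonal matrix `rho`.
#' @export
spearman_matrix <- function(x, ids = NULL) {
  if (inherits(x, "imputed_ensemble")) {
    if (is.null(ids)) ids <- measure_ids(x$datasets[[1]])
    pooled <- pool_over_ensemble(function(tb) spearman_matrix(tb, ids)$rho, x)
    return(structure(list(measure_ids = ids, rho = pooled$mean),
                     class = "correlation_matrix"))
  }
  stopifnot(inherits(x, "measure_table"))
  if (is.null(ids)) ids <- measure_ids(x)
  v <- x$values[, ids, drop = FALSE]
  if (anyNA(v)) stop("spearman_matrix needs complete data; impute first")
  const <- apply(v, 2, function(col) length(unique(col)) == 1)
  if (any(const))
    stop("Spearman correlation undefined for constant measure: ",
         paste(ids[const], collapse = ", "))
  rho <- stats::cor(v, method = "spearman")
  structure(list(measure_ids = ids, rho = rho),
            class = "correlation_matrix")
}

#' @export
print.correlation_matrix <- function(x, ...) {
  off <- x$rho[upper.tri(x$rho)]
  cat("<correlation_matrix> ", length(x$measure_ids), " measures; max |rho| ",
      round(max(abs(off)), 3), "\n", sep = "")
  invisible(x)
}

## rule-determined victim of one violating pair:
## rule 2 (drop the dual-task twin) when the two measures are the ST/DT
## instantiation of the same base measure, otherwise rule 1 (drop the
## smaller-|SMD| member; ties broken towards the lexicographically
## larger id so the outcome is deterministic).
.pair_victim <- function(id_a, id_b, cat_map, abs_smd) {
  a <- cat_map[[id_a]]; b <- cat_map[[id_b]]
  if (a$base_name == b$base_name && a$domain == b$domain &&
      xor(a$is_dual_task, b$is_dual_task)) {
    victim <- if (a$is_dual_task) id_a else id_b
    return(list(victim = victim, rule = "dual_task"))
  }
  sa <- abs_smd[[id_a]]; sb <- abs_smd[[id_b]]
  victim <- if (sa < sb) id_a
            else if (sb < sa) id_b
            else max(id_a, id_b)
  list(victim = victim, rule = "smaller_smd")
}

## exact minimum-removal solver for one connected component of the
## violation graph.  A removal is admissible only as the rule-designated
## victim of a pair whose two members both still survive; the search
## enumerates admissible removal sequences with memoisation on the
## surviving set and keeps the terminal survivor sets, preferring
## (1) fewest removals, (2) largest surviving total |SMD|,
## (3) lexicographically smallest sorted removal list.
.solve_component <- function(nodes, pairs, abs_smd) {
  memo <- new.env(parent = emptyenv())
  empty_removals <- data.frame(removed_id = character(0),
                               kept_id = character(0), rho = numeric(0),
                               rule_applied = character(0))
  best <- function(surv) {
    key <- paste(sort(surv), collapse = "|")
    if (!is.null(memo[[key]])) return(memo[[key]])
    active <- pairs[pairs$a %in% surv & pairs$b %in% surv, , drop = FALSE]
    if (!nrow(active)) {
      res <- list(survivors = surv, removals = empty_removals)
    } else {
      victims <- unique(active$victim)
      cands <- lapply(victims, function(v) {
        sub <- best(setdiff(surv, v))
        # attribute the removal to the strongest active pair that
        # designates this victim
        sanct <- active[active$victim == v, , drop = FALSE]
        sanct <- sanct[order(-abs(sanct$rho), sanct$a, sanct$b),
                       , drop = FALSE][1, ]
        step <- data.frame(removed_id = v,
                           kept_id = if (sanct$a == v) sanct$b else sanct$a,
                           rho = sanct$rho, rule_applied = sanct$rule)
        list(survivors = sub$survivors,
             removals = rbind(step, sub$removals))
      })
      sizes <- vapply(cands, function(c) length(c$survivors), 1L)
      cands <- cands[sizes == max(sizes)]
      if (length(cands) > 1) {
        tot <- vapply(cands, function(c) sum(abs_smd[c$survivors]), 1)
        cands <- cands[abs(tot - max(tot)) < 1e-12]
      }
      if (length(cands) > 1) {
        keys <- vapply(cands, function(c)
          paste(sort(c$removals$removed_id), collapse = "|"), "")
        cands <- cands[order(keys)]
      }
      res <- cands[[1]]
    }
    memo[[key]] <- res
    res
  }
  best(nodes)
}

#' Prune correlated measures
#'
#' Removes measures among a sensitive set until no surviving pair has
#' absolute Spearman correlation above the threshold.  Which member of
#' a violating pair is removed is fixed by two rules: the dual-task twin
#' goes when the pair is the single-/dual-task instantiation of the same
#' base measure (rule `dual_task`); otherwise the member with the
#' smaller absolute SMD goes (rule `smaller_smd`).  Among all
#' rule-respecting removal sequences the pruning keeps a minimum-removal
#' solution (computed exactly per connected component of the violation
#' graph), so a measure is never discarded when an earlier removal
#' already resolved its conflicts.
#'
#' @param effects data frame from [effect_size_table()] /
#'   [filter_by_smd()] covering the candidate measures (its row order
#'   defines the survivor ordering).
#' @param corr a `correlation_matrix` over the same measure ids.
#' @param cat a `measure_catalogue` covering the ids (for the dual-task
#'   rule).
#' @param threshold redundancy threshold in `(0, 1)`; pairs with
#'   `|rho|` strictly above it are redundant (default 0.70).
#' @param max_exact largest component solved exactly; larger components
#'   fall back to a greedy descending-`|rho|` pass (default 18).
#' @return A list of class `pruning_audit`: `survivors` (ids, in the
#'   `effects` row order), `removed` (data frame `removed_id`,
#'   `kept_id`, `rho`, `rule_applied`), and `threshold`.
#' @export
prune_redundant <- function(effects, corr, cat, threshold = 0.70,
                            max_exact = 18) {
  stopifnot(inherits(corr, "correlation_matrix"),
            threshold > 0, threshold < 1)
  ids <- effects$measure_id
  if (!setequal(ids, corr$measure_ids))
    stop("effects and correlation matrix cover different measure ids")
  cat_sub <- cat[match(ids, cat$measure_id), , drop = FALSE]
  if (anyNA(cat_sub$measure_id))
    stop("catalogue does not cover all candidate measure ids")
  cat_map <- split(cat_sub, seq_len(nrow(cat_sub)))
  names(cat_map) <- ids
  abs_smd <- stats::setNames(effects$abs_smd, ids)

  rho <- corr$rho[ids, ids, drop = FALSE]
  viol <- which(abs(rho) > threshold & upper.tri(rho), arr.ind = TRUE)
  pairs <- data.frame(a = ids[viol[, 1]], b = ids[viol[, 2]],
                      rho = rho[viol], stringsAsFactors = FALSE)
  if (nrow(pairs)) {
    vr <- lapply(seq_len(nrow(pairs)), function(k)
      .pair_victim(pairs$a[k], pairs$b[k], cat_map, abs_smd))
    pairs$victim <- vapply(vr, `[[`, "", "victim")
    pairs$rule <- vapply(vr, `[[`, "", "rule")
  } else {
    pairs$victim <- character(0); pairs$rule <- character(0)
  }

  ## connected components of the violation graph
  removed_ids <- character(0)
  audit <- data.frame(removed_id = character(0), kept_id = character(0),
                      rho = numeric(0), rule_applied = character(0))
  if (nrow(pairs)) {
    comp <- stats::setNames(seq_along(ids), ids)
    for (k in seq_len(nrow(pairs))) {
      ca <- comp[pairs$a[k]]; cb <- comp[pairs$b[k]]
      comp[comp == cb] <- ca
    }
    for (cc in unique(comp[c(pairs$a, pairs$b)])) {
      nodes <- names(comp)[comp == cc]
      sub <- pairs[pairs$a %in% nodes & pairs$b %in% nodes, , drop = FALSE]
      if (length(nodes) <= max_exact) {
        sol <- .solve_component(nodes, sub, abs_smd)
        removed_ids <- c(removed_ids, sol$removals$removed_id)
        audit <- rbind(audit, sol$removals)
      } else {
        ## greedy fallback: process by descending |rho|, recheck
        surv <- nodes
        sub <- sub[order(-abs(sub$rho), sub$a, sub$b), , drop = FALSE]
        repeat {
          act <- sub[sub$a %in% surv & sub$b %in% surv, , drop = FALSE]
          if (!nrow(act)) break
          v <- act$victim[1]
          audit <- rbind(audit, data.frame(
            removed_id = v,
            kept_id = if (act$a[1] == v) act$b[1] else act$a[1],
            rho = act$rho[1], rule_applied = act$rule[1]))
          surv <- setdiff(surv, v)
        }
        removed_ids <- c(removed_ids, setdiff(nodes, surv))
      }
    }
  }

  survivors <- setdiff(ids, removed_ids)
  stopifnot(!any(abs(rho[survivors, survivors])[
    upper.tri(diag(length(survivors)))] > threshold))
  rownames(audit) <- NULL
  structure(list(survivors = ids[ids %in% survivors], removed = audit,
                 threshold = threshold),
            class = "pruning_audit")
}

#' @export
print.pruning_audit <- function(x, ...) {
  cat("<pruning_audit> ", length(x$survivors), " survivors, ",
      nrow(x$removed), " removed (threshold |rho| > ", x$threshold,
      ")\n", sep = "")
  if (nrow(x$removed)) print(table(rule = x$removed$rule_applied))
  invisible(x)
}
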