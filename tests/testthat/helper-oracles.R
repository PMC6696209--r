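# Independent oracles used to cross-check the package implementations.
# Each is written directly from the defining formula, independently of
# the code path it checks.

# standardized mean difference, both denominators, spelled out longhand
oracle_smd_paper <- function(m1, s1, n1, m2, s2, n2) {
  inner <- s1 * s1 / n1 + s2 * s2 / n2
  scale <- (n1 * n2) / (n1 + n2)
  (m1 - m2) / sqrt(inner * scale)
}

oracle_smd_cohen <- function(m1, s1, n1, m2, s2, n2) {
  num <- (n1 - 1) * s1 * s1 + (n2 - 1) * s2 * s2
  (m1 - m2) / sqrt(num / (n1 + n2 - 2))
}

# Spearman rho via the rank-difference formula (average ranks); reduces
# to 1 - 6 sum(d^2) / (n(n^2-1)) when there are no ties
oracle_spearman <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  if (!anyDuplicated(rx) && !anyDuplicated(ry)) {
    n <- length(x)
    1 - 6 * sum((rx - ry)^2) / (n * (n^2 - 1))
  } else {
    sum((rx - mean(rx)) * (ry - mean(ry))) /
      sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  }
}

# Benjamini-Hochberg step-up, literally: sort ascending, p * m / i,
# enforce monotonicity from the largest down, cap at 1
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  for (i in (m - 1):1) adj[i] <- min(adj[i], adj[i + 1])
  out <- numeric(m)
  out[o] <- pmin(adj, 1)
  out
}

# ICC(2,1) through R's own two-way ANOVA fit rather than hand-rolled
# mean squares
oracle_icc_aov <- function(pairs) {
  n <- nrow(pairs); k <- ncol(pairs)
  df <- data.frame(y = as.vector(pairs),
                   subj = factor(rep(seq_len(n), k)),
                   sess = factor(rep(seq_len(k), each = n)))
  ms <- summary(stats::aov(y ~ subj + sess, data = df))[[1]][["Mean Sq"]]
  msr <- ms[1]; msc <- ms[2]; mse <- ms[3]
  (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
}

# victim of a violating pair under the two pruning rules (independent
# re-statement)
oracle_victim <- function(a, b, cat, smd) {
  ca <- cat[cat$measure_id == a, ]; cb <- cat[cat$measure_id == b, ]
  if (ca$base_name == cb$base_name && ca$domain == cb$domain &&
      xor(ca$is_dual_task, cb$is_dual_task)) {
    return(list(victim = if (ca$is_dual_task) a else b, rule = "dual_task"))
  }
  v <- if (smd[[a]] < smd[[b]]) a else if (smd[[b]] < smd[[a]]) b
       else max(a, b)
  list(victim = v, rule = "smaller_smd")
}

# exhaustive search over every admissible removal sequence: a measure
# may be removed only as the rule-designated victim of a pair whose two
# members both still survive; among all terminal survivor sets prefer
# most survivors, then largest surviving total |SMD|, then the
# lexicographically smallest sorted removal list
oracle_prune_exhaustive <- function(ids, rho, cat, smd, threshold) {
  terminals <- list()
  recurse <- function(surv) {
    viol <- list()
    for (i in seq_along(surv)) for (j in seq_along(surv)) {
      if (i < j && abs(rho[surv[i], surv[j]]) > threshold)
        viol[[length(viol) + 1]] <- c(surv[i], surv[j])
    }
    if (!length(viol)) {
      terminals[[length(terminals) + 1]] <<- surv
      return(invisible())
    }
    victims <- unique(vapply(viol, function(pr)
      oracle_victim(pr[1], pr[2], cat, smd)$victim, ""))
    for (v in victims) recurse(setdiff(surv, v))
  }
  recurse(ids)
  sizes <- vapply(terminals, length, 1L)
  keep <- terminals[sizes == max(sizes)]
  tot <- vapply(keep, function(s) sum(smd[s]), 1)
  keep <- keep[abs(tot - max(tot)) < 1e-12]
  keys <- vapply(keep, function(s) paste(sort(setdiff(ids, s)),
                                         collapse = "|"), "")
  sort(keep[[order(keys)[1]]])
}

# small complete measure_table from a values matrix
make_toy_table <- function(values, group = NULL) {
  if (is.null(colnames(values)))
    colnames(values) <- paste0("m", seq_len(ncol(values)))
  if (is.null(group))
    group <- rep(c("PD", "HC"), length.out = nrow(values))
  measure_table(values, group)
}

# minimal catalogue whose measure ids are Gait_ST.<base> / Gait_DT.<base>
make_toy_catalogue <- function(base_names, tasks = rep("Gait_ST",
                                                       length(base_names))) {
  new_catalogue(base_name = base_names,
                domain = rep("Gait", length(base_names)),
                task = tasks,
                impairment_direction = rep("higher_is_worse",
                                           length(base_names)))
}

# random small pruning instance: 3-6 measures, some of them ST/DT twins
# of the same base measure, a random symmetric rho matrix with a few
# planted violations, random |SMD| values
random_prune_instance <- function(seed, threshold = 0.7) {
  set.seed(seed)
  n_base <- sample(2:4, 1)
  base <- paste0("b", seq_len(n_base))
  dt <- base[stats::runif(n_base) < 0.4]
  cat <- make_toy_catalogue(c(base, dt),
                            c(rep("Gait_ST", n_base),
                              rep("Gait_DT", length(dt))))
  ids <- cat$measure_id
  p <- length(ids)
  rho <- diag(p)
  dimnames(rho) <- list(ids, ids)
  for (i in seq_len(p)) for (j in seq_len(p)) {
    if (i < j) {
      r <- if (stats::runif(1) < 0.45)
        stats::runif(1, threshold + 0.02, 0.95) * sample(c(-1, 1), 1)
      else stats::runif(1, -0.5, 0.5)
      rho[i, j] <- rho[j, i] <- r
    }
  }
  smd <- stats::setNames(round(stats::runif(p, 0.5, 1.5), 3), ids)
  effects <- data.frame(measure_id = ids, abs_smd = unname(smd))
  corr <- structure(list(measure_ids = ids, rho = rho),
                    class = "correlation_matrix")
  list(ids = ids, rho = rho, cat = cat, smd = smd,
       effects = effects, corr = corr)
}
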