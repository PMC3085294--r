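# Independent enumeration oracle for rank-test p-values: iterate over every
# distinct assignment of the pooled observations to groups of the observed
# sizes and tabulate the statistic of each assignment using R's own test
# functions (a code path disjoint from the package's implementations).
enumerate_assignments <- function(ns) {
  N <- sum(ns)
  out <- list()
  rec <- function(avail, gi, acc) {
    if (gi == length(ns)) {
      out[[length(out) + 1]] <<- c(acc, list(avail))
      return(invisible())
    }
    cmb <- utils::combn(avail, ns[gi])
    for (j in seq_len(ncol(cmb)))
      rec(setdiff(avail, cmb[, j]), gi + 1L, c(acc, list(cmb[, j])))
  }
  rec(seq_len(N), 1L, list())
  out
}

kw_perm_oracle <- function(groups) {
  pooled <- unlist(groups, use.names = FALSE)
  ns <- lengths(groups)
  H_obs <- unname(stats::kruskal.test(
    pooled, factor(rep(seq_along(ns), ns)))$statistic)
  assigns <- enumerate_assignments(ns)
  Hs <- vapply(assigns, function(idx) {
    labels <- integer(length(pooled))
    for (g in seq_along(idx)) labels[idx[[g]]] <- g
    unname(stats::kruskal.test(pooled, factor(labels))$statistic)
  }, numeric(1))
  mean(Hs >= H_obs - 1e-9)
}

mw_perm_oracle <- function(a, b) {
  pooled <- c(a, b)
  n1 <- length(a)
  assigns <- utils::combn(length(pooled), n1)
  u_of <- function(x, y) sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
  U_obs <- u_of(a, b)
  Us <- apply(assigns, 2, function(idx)
    u_of(pooled[idx], pooled[-idx]))
  # two-sided: double the smaller tail (the convention of exact wilcox.test)
  p <- 2 * min(mean(Us <= U_obs + 1e-9), mean(Us >= U_obs - 1e-9))
  min(p, 1)
}

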