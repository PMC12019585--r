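# Shared fixtures for the test suite. Everything is generated in code; the
# reduced integrator settings (step 1 day, loose tolerance, few years) keep
# the default run fast while exercising the full model.

fast_steady <- function(state0, drivers, params, tol = 1e-3, max_years = 25,
                        step = 1, ...) {
  run_to_steady_state(state0, drivers, params, tol = tol,
                      max_years = max_years, step = step, ...)
}

# small ledger on a chain of real compartment names, for index tests
chain_ledger <- function(flows) {
  # flows: named list donor->recipient = value, names like "a|b"
  nodes <- unique(unlist(strsplit(names(flows), "|", fixed = TRUE)))
  m <- matrix(0, length(nodes), length(nodes),
              dimnames = list(nodes, nodes))
  for (nm in names(flows)) {
    pr <- strsplit(nm, "|", fixed = TRUE)[[1]]
    m[pr[1], pr[2]] <- flows[[nm]]
  }
  make_ledger(m)
}

# random small ledger over a fixed set of compartments with guaranteed
# external anchoring (phytoplankton fed by nitrate)
random_ledger <- function(seed, n_extra_flows = 8) {
  set.seed(seed)
  nodes <- c("surface_nitrate", "surface_phyt", "omni_zooplankton",
             "carn_zooplankton", "planktivorous_fish", "surface_detritus")
  m <- matrix(0, 6, 6, dimnames = list(nodes, nodes))
  m["surface_nitrate", "surface_phyt"] <- runif(1, 5, 20)
  living <- c("omni_zooplankton", "carn_zooplankton", "planktivorous_fish")
  feed_pairs <- rbind(
    c("surface_phyt", "omni_zooplankton"),
    c("surface_detritus", "omni_zooplankton"),
    c("omni_zooplankton", "carn_zooplankton"),
    c("surface_phyt", "carn_zooplankton"),
    c("omni_zooplankton", "planktivorous_fish"),
    c("carn_zooplankton", "planktivorous_fish"),
    c("surface_detritus", "carn_zooplankton"),
    c("surface_phyt", "planktivorous_fish"))
  keep <- sample(nrow(feed_pairs), min(n_extra_flows, nrow(feed_pairs)))
  # always keep at least one inflow per living consumer
  keep <- union(keep, c(1, 3, 5))
  for (i in keep) m[feed_pairs[i, 1], feed_pairs[i, 2]] <- runif(1, 0.1, 10)
  make_ledger(m)
}

# brute-force oracles ---------------------------------------------------

# iterative trophic-level solve (power iteration on the diet recursion)
oracle_trophic_levels <- function(ledger, iters = 400) {
  TT <- ledger$T
  cn <- rownames(TT)
  consv <- setdiff(living_names(), producer_names())
  tl <- stats::setNames(rep(1, length(cn)), cn)
  for (it in seq_len(iters)) {
    new <- tl
    for (j in intersect(consv, cn)) {
      inflow <- TT[, j]
      tot <- sum(inflow)
      if (tot > 0) new[[j]] <- 1 + sum(inflow / tot * tl)
    }
    tl <- new
  }
  tl
}

# truncated path-series oracle for the dominance of indirect effects
oracle_indirect_dominance <- function(ledger, kmax = 400) {
  TT <- ledger$T
  denom <- colSums(TT) + ledger$imports
  G <- sweep(TT, 2, pmax(denom, .Machine$double.eps), "/")
  G[, denom <= 0] <- 0
  acc <- matrix(0, nrow(G), ncol(G))
  Gk <- G
  for (k in 2:kmax) {
    Gk <- Gk %*% G
    acc <- acc + Gk
  }
  sum(acc) / sum(G)
}

# direct-sum oracle for ascendancy and capacity
oracle_ascendancy <- function(ledger) {
  TT <- ledger$T
  tot <- sum(TT)
  A <- 0; C <- 0
  for (i in seq_len(nrow(TT))) {
    for (j in seq_len(ncol(TT))) {
      tij <- TT[i, j]
      if (tij > 0) {
        A <- A + tij * log2(tij * tot / (sum(TT[i, ]) * sum(TT[, j])))
        C <- C - tij * log2(tij / tot)
      }
    }
  }
  list(A = A, C = C)
}
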