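# Shared fixtures and independent oracles for the kelpfe suite.

# Element-wise relative comparison. Used for mol/L-scale quantities,
# where all.equal's tolerance would silently degrade to an absolute
# check (its scale falls back to absolute when mean(|expected|) is
# below the tolerance).
expect_rel <- function(actual, expected, tol) {
  expect_lt(max(abs(actual / expected - 1)), tol)
}

# Conditions of the standard seven-treatment experiment.
std_constants <- function() fe_edta_constants(4.98e-8, 8.01e-7, 0.163)
std_medium <- function() buffer_medium("100uM", 0, "7.25nM")
std_additions <- c(0, 1, 2.5, 5, 10, 20, 40) * 1e-6
printed_fe_prime_nM <- c(0.01, 1.85, 4.67, 9.56, 20.2, 45.2, 120)

# Brute-force SSE grid search for the Michaelis-Menten fit: the oracle
# stays independent of the least-squares path it checks.
mm_grid_oracle <- function(s, v, vmax_range, km_range, n_grid = 200) {
  vmax_grid <- seq(vmax_range[1], vmax_range[2], length.out = n_grid)
  km_grid <- seq(km_range[1], km_range[2], length.out = n_grid)
  best <- c(vmax = NA_real_, km = NA_real_)
  best_sse <- Inf
  for (vm in vmax_grid) {
    for (km in km_grid) {
      sse <- sum((v - vm * s / (km + s))^2)
      if (sse < best_sse) {
        best_sse <- sse
        best <- c(vmax = vm, km = km)
      }
    }
  }
  list(par = best, sse = best_sse,
       res_vmax = diff(vmax_range) / (n_grid - 1),
       res_km = diff(km_range) / (n_grid - 1))
}

# Bisection on the forward speciation map, an independent route to the
# inverse design calculation.
invert_by_bisection <- function(target, medium, constants,
                                tol = 1e-12) {
  lo <- 0
  hi <- medium$edta_total * (1 - 1e-12)
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (fe_prime(mid, medium, constants)$fe_prime < target) {
      lo <- mid
    } else {
      hi <- mid
    }
    if ((hi - lo) <= tol * max(hi, 1e-30)) break
  }
  (lo + hi) / 2
}

# All letter assignments consistent with a significance pattern, by
# exhaustive enumeration over subsets; returns the minimal consistent
# number of letters (groups <= 8).
min_letters_by_enumeration <- function(groups, sig_pairs) {
  k <- length(groups)
  not_sig <- function(a, b) {
    !any((sig_pairs$group_a == a & sig_pairs$group_b == b) |
           (sig_pairs$group_a == b & sig_pairs$group_b == a))
  }
  # candidate letters = subsets within which no pair is significant
  subsets <- list()
  for (m in 1:(2^k - 1)) {
    members <- groups[bitwAnd(m, 2^(seq_len(k) - 1)) > 0]
    ok <- TRUE
    if (length(members) > 1) {
      cmb <- utils::combn(members, 2)
      for (j in seq_len(ncol(cmb))) {
        if (!not_sig(cmb[1, j], cmb[2, j])) { ok <- FALSE; break }
      }
    }
    if (ok) subsets[[length(subsets) + 1]] <- members
  }
  covers <- function(chosen) {
    # every group covered, every non-significant pair shares a letter,
    # no significant pair shares a letter (guaranteed by construction)
    if (!all(groups %in% unlist(chosen))) return(FALSE)
    for (a in groups) for (b in groups) {
      if (a < b && not_sig(a, b)) {
        shared <- any(vapply(chosen, function(sb) {
          a %in% sb && b %in% sb
        }, logical(1)))
        if (!shared) return(FALSE)
      }
    }
    TRUE
  }
  for (nl in 1:k) {
    idx <- utils::combn(length(subsets), nl)
    for (j in seq_len(ncol(idx))) {
      if (covers(subsets[idx[, j]])) return(nl)
    }
  }
  k
}

# Letter display consistency: shared letter <=> pair not significant.
letters_consistent <- function(letters_map, pairwise, alpha) {
  for (i in seq_len(nrow(pairwise))) {
    a <- pairwise$group_a[i]
    b <- pairwise$group_b[i]
    shared <- length(intersect(
      strsplit(letters_map[[a]], "")[[1]],
      strsplit(letters_map[[b]], "")[[1]])) > 0
    sig <- pairwise$p_adj[i] < alpha
    if (shared == sig) return(FALSE)
  }
  TRUE
}
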