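# Integrated information (IIT 3.0 style): candidate subsystems, cause/effect
# repertoires, small phi via exhaustive purview/partition search, big Phi via
# unidirectional system cuts, and lifetime maximization.
#
# Conventions, pinned for reproducibility:
#  * subsystem states are indexed little-endian over the sorted member units;
#  * repertoire distances use the earth mover's distance with Hamming ground
#    metric over purview states;
#  * cause repertoires multiply the per-mechanism-node likelihoods (virtual
#    elements) and renormalize; effect repertoires factorize over purview
#    nodes; unconstrained inputs are marginalized uniformly (interventional,
#    perturbation-based probabilities);
#  * among equal-phi purviews the larger, then lexicographically smallest,
#    purview is kept; among equal-Phi subsets the smaller, then
#    lexicographically smallest, subset is kept.

PHI_TOL <- 1e-10

#' Exact earth mover's distance
#'
#' Solves the transportation problem between two distributions over the same
#' state space by successive-shortest-path min-cost flow. Exact for the
#' small state spaces used here (at most 2^8 states).
#'
#' @param p,q Numeric distributions (same length, equal totals).
#' @param cost Ground-distance matrix, `cost[i, j]` = cost of moving mass
#'   from state `i` to state `j`.
#' @return The minimal transport cost (numeric scalar).
#' @examples
#' emd(c(1, 0), c(0, 1), matrix(c(0, 1, 1, 0), 2))
#' @export
emd <- function(p, q, cost) {
  stopifnot(length(p) == length(q), all(dim(cost) == c(length(p), length(q))))
  r <- p - q
  tol <- 1e-12
  src <- which(r > tol)
  snk <- which(r < -tol)
  if (length(src) == 0L || length(snk) == 0L) {
    return(0)
  }
  min_cost_transport(r[src], -r[snk], cost[src, snk, drop = FALSE])
}

# exact min-cost transportation: supply (length ns) to demand (length nt)
# with cost matrix C; totals must match within tolerance
min_cost_transport <- function(supply, demand, C) {
  ns <- length(supply); nt <- length(demand)
  stopifnot(abs(sum(supply) - sum(demand)) < 1e-8)
  flow <- matrix(0, ns, nt)
  tol <- 1e-12
  while (sum(supply) > 1e-9) {
    # Bellman-Ford over nodes [sources 1..ns, sinks ns+1..ns+nt]
    n_nodes <- ns + nt
    dist <- rep(Inf, n_nodes)
    parent <- rep(NA_integer_, n_nodes)
    dist[which(supply > tol)] <- 0
    for (iter in seq_len(n_nodes)) {
      changed <- FALSE
      for (i in seq_len(ns)) {
        if (!is.finite(dist[i])) next
        relax <- dist[i] + C[i, ]
        upd <- relax < dist[ns + seq_len(nt)] - tol
        if (any(upd)) {
          dist[ns + which(upd)] <- relax[upd]
          parent[ns + which(upd)] <- i
          changed <- TRUE
        }
      }
      for (j in seq_len(nt)) {
        if (!is.finite(dist[ns + j])) next
        back <- which(flow[, j] > tol)
        for (i in back) {
          if (dist[ns + j] - C[i, j] < dist[i] - tol) {
            dist[i] <- dist[ns + j] - C[i, j]
            parent[i] <- ns + j
            changed <- TRUE
          }
        }
      }
      if (!changed) break
    }
    cand <- which(demand > tol)
    j_best <- cand[which.min(dist[ns + cand])]
    if (!is.finite(dist[ns + j_best])) {
      stop_animats("transportation problem is infeasible")
    }
    # backtrack to find the path and its bottleneck
    path <- list()
    node <- ns + j_best
    bottleneck <- demand[j_best]
    while (!is.na(parent[node])) {
      prev <- parent[node]
      if (node > ns) {
        path[[length(path) + 1L]] <- c(prev, node - ns, 1L)  # forward arc
      } else {
        path[[length(path) + 1L]] <- c(node, prev - ns, -1L)  # backward arc
        bottleneck <- min(bottleneck, flow[node, prev - ns])
      }
      node <- prev
    }
    bottleneck <- min(bottleneck, supply[node])
    for (arc in path) {
      flow[arc[1L], arc[2L]] <- flow[arc[1L], arc[2L]] + arc[3L] * bottleneck
    }
    supply[node] <- supply[node] - bottleneck
    demand[j_best] <- demand[j_best] - bottleneck
  }
  sum(flow * C)
}

# Hamming distances between all pairs of k-bit states
hamming_cost <- function(k) {
  if (k == 0L) return(matrix(0, 1L, 1L))
  states <- states_matrix(k)
  m <- matrix(0L, 2L^k, 2L^k)
  for (b in seq_len(k)) {
    m <- m + outer(states[, b], states[, b], FUN = function(a, b) as.integer(a != b))
  }
  m
}

#' Condition a brain into a candidate subsystem
#'
#' Builds the interventional transition rule of a candidate set of
#' computational units: sensors are clamped to their observed state and all
#' non-member, non-sensor units are frozen as background at their observed
#' state. Member units are perturbed into each of their `2^k` states and the
#' brain is stepped once per state.
#'
#' @param brain A [markov_brain()].
#' @param units Unit ids of the candidate set (non-sensor units).
#' @param state Observed full brain state: a 0/1 vector of length
#'   `n_units`, or the packed integer the trial log stores.
#' @param max_units Resource guard on the candidate-set size.
#' @return A `candidate_system`: node transition matrix (`2^k` rows, `k`
#'   columns of next-state probabilities, deterministic 0/1 here), member
#'   units, and their current state.
#' @examples
#' b <- markov_brain(arch_spec("smallbrain"), list())
#' condition_tpm(b, units = 3:4, state = rep(0L, 6))
#' @export
condition_tpm <- function(brain, units, state, max_units = 8L) {
  stopifnot(inherits(brain, "markov_brain"))
  units <- sort(as.integer(units))
  ns <- brain$arch$n_sensors
  if (any(units <= ns)) stop_animats("candidate sets contain computational units only (no sensors)")
  if (length(units) > max_units) {
    stop_animats("candidate set of ", length(units), " units exceeds the limit of ", max_units)
  }
  if (length(state) == 1L) state <- int_to_bits(state, brain$n_units)
  stopifnot(length(state) == brain$n_units)
  k <- length(units)
  states <- states_matrix(k)
  tpm <- matrix(0, 2L^k, k)
  for (i in seq_len(2L^k)) {
    full <- as.integer(state)
    full[units] <- states[i, ]
    tpm[i, ] <- brain_step(brain, full)[units]
  }
  new_candidate_system(tpm, units, as.integer(state)[units])
}

new_candidate_system <- function(tpm, units, state) {
  structure(list(tpm = tpm, units = units, state = as.integer(state),
                 k = length(units)),
            class = "candidate_system")
}

#' @export
print.candidate_system <- function(x, ...) {
  cat(sprintf("<candidate_system> %d units (%s), state %s\n", x$k,
              paste(x$units, collapse = ","), paste(x$state, collapse = "")))
  invisible(x)
}

# --- repertoires (positions are indices 1..k within the subsystem) ---------

# likelihood of mechanism node `pos` having its observed value, per past state
node_likelihood <- function(sys, pos) {
  if (sys$state[pos] == 1L) sys$tpm[, pos] else 1 - sys$tpm[, pos]
}

cause_repertoire <- function(sys, mech, purview) {
  if (length(purview) == 0L) return(1)
  np <- length(purview)
  if (length(mech) == 0L) {
    return(rep(1 / 2^np, 2^np))
  }
  states <- states_matrix(sys$k)
  pidx <- as.vector(states[, purview, drop = FALSE] %*% 2^(seq_len(np) - 1L)) + 1L
  rep_total <- rep(1, 2^np)
  for (pos in mech) {
    L <- node_likelihood(sys, pos)
    cr_i <- vapply(seq_len(2^np), function(z) mean(L[pidx == z]), numeric(1))
    rep_total <- rep_total * cr_i
  }
  s <- sum(rep_total)
  if (s < 1e-300) return(NULL)
  rep_total / s
}

effect_repertoire <- function(sys, mech, purview) {
  if (length(purview) == 0L) return(1)
  states <- states_matrix(sys$k)
  rows <- if (length(mech) == 0L) {
    seq_len(2^sys$k)
  } else {
    which(apply(states[, mech, drop = FALSE], 1L,
                function(b) all(b == sys$state[mech])))
  }
  p1 <- vapply(purview, function(j) mean(sys$tpm[rows, j]), numeric(1))
  np <- length(purview)
  pstates <- states_matrix(np)
  apply(pstates, 1L, function(z) prod(ifelse(z == 1L, p1, 1 - p1)))
}

repertoire <- function(sys, mech, purview, direction) {
  if (direction == "cause") {
    cause_repertoire(sys, mech, purview)
  } else {
    effect_repertoire(sys, mech, purview)
  }
}

# combine repertoires over disjoint purviews z1 and z2 into sort(c(z1, z2))
combine_reps <- function(r1, z1, r2, z2) {
  z <- sort(c(z1, z2))
  if (length(z) == 0L) return(1)
  np <- length(z)
  zstates <- states_matrix(np)
  i1 <- match(z1, z); i2 <- match(z2, z)
  idx1 <- if (length(z1)) {
    as.vector(zstates[, i1, drop = FALSE] %*% 2^(seq_along(z1) - 1L)) + 1L
  } else {
    rep(1L, 2^np)
  }
  idx2 <- if (length(z2)) {
    as.vector(zstates[, i2, drop = FALSE] %*% 2^(seq_along(z2) - 1L)) + 1L
  } else {
    rep(1L, 2^np)
  }
  v1 <- if (is.null(r1)) NULL else r1[idx1]
  v2 <- if (is.null(r2)) NULL else r2[idx2]
  if (is.null(v1) || is.null(v2)) return(NULL)
  v1 * v2
}

# minimum-information-partition phi for one mechanism/purview/direction
mip_phi <- function(sys, mech, purview, direction, whole) {
  cost <- hamming_cost(length(purview))
  best <- Inf
  mech_subsets <- c(list(integer(0)), subsets_of(mech))
  purv_subsets <- c(list(integer(0)), subsets_of(purview))
  for (y1 in mech_subsets) {
    y2 <- setdiff(mech, y1)
    for (z1 in purv_subsets) {
      z2 <- setdiff(purview, z1)
      trivial <- (length(y1) == 0L && length(z1) == 0L) ||
        (length(y2) == 0L && length(z2) == 0L)
      if (trivial) next
      r1 <- repertoire(sys, y1, z1, direction)
      r2 <- repertoire(sys, y2, z2, direction)
      part <- combine_reps(r1, z1, r2, z2)
      if (is.null(part)) next
      d <- emd(whole, part, cost)
      if (d < best) best <- d
      if (best < PHI_TOL) return(0)
    }
  }
  if (!is.finite(best)) 0 else best
}

#' Integrated information of a single mechanism (small phi)
#'
#' Exhaustively searches, separately for the cause (t-1) and effect (t+1)
#' direction, over all purviews and all bipartitions of the mechanism-
#' purview pair for the maximally irreducible cause/effect repertoire. The
#' repertoire distance is the earth mover's distance over purview states;
#' phi is the minimum of the cause and effect values.
#'
#' @param system A `candidate_system` from [condition_tpm()].
#' @param mechanism Unit ids (absolute) of the mechanism, a subset of the
#'   system's units.
#' @return A list: `phi`, and per direction the maximizing purview (absolute
#'   unit ids), its repertoire, and its phi value.
#' @examples
#' b <- markov_brain(arch_spec("smallbrain"), list())
#' sys <- condition_tpm(b, 3:4, rep(0L, 6))
#' small_phi(sys, 3L)$phi
#' @export
small_phi <- function(system, mechanism) {
  stopifnot(inherits(system, "candidate_system"))
  mech <- match(sort(as.integer(mechanism)), system$units)
  if (anyNA(mech) || length(mech) == 0L) {
    stop_animats("mechanism must be a non-empty subset of the system's units")
  }
  out <- list(phi = 0)
  for (direction in c("cause", "effect")) {
    best_phi <- 0; best_purview <- NULL; best_rep <- NULL
    for (purview in subsets_of(seq_len(system$k))) {
      whole <- repertoire(system, mech, purview, direction)
      if (is.null(whole)) next
      phi_z <- mip_phi(system, mech, purview, direction, whole)
      replace <- phi_z > best_phi + PHI_TOL ||
        (abs(phi_z - best_phi) <= PHI_TOL && !is.null(best_purview) &&
           length(purview) > length(best_purview) && phi_z > PHI_TOL)
      if ((is.null(best_purview) && phi_z > PHI_TOL) || replace) {
        best_phi <- phi_z; best_purview <- purview; best_rep <- whole
      }
    }
    out[[direction]] <- list(phi = best_phi,
                             purview = system$units[best_purview],
                             repertoire = best_rep)
  }
  out$phi <- min(out$cause$phi, out$effect$phi)
  out
}

# expand a repertoire over `purview` (positions) to the full subsystem space:
# cause side pads with the uniform distribution, effect side with the
# unconstrained effect repertoire of the remaining nodes
expand_repertoire <- function(sys, rep, purview, direction) {
  rest <- setdiff(seq_len(sys$k), purview)
  pad <- if (direction == "cause") {
    if (length(rest) == 0L) 1 else rep(1 / 2^length(rest), 2^length(rest))
  } else {
    effect_repertoire(sys, integer(0), rest)
  }
  combine_reps(rep, purview, pad, rest)
}

null_concept <- function(sys) {
  list(
    cause = expand_repertoire(sys, rep(1, 1), integer(0), "cause"),
    effect = expand_repertoire(sys, rep(1, 1), integer(0), "effect")
  )
}

# all concepts (mechanisms with phi > 0) of a candidate system
constellation <- function(sys) {
  out <- list()
  for (mech_pos in subsets_of(seq_len(sys$k))) {
    res <- small_phi(sys, sys$units[mech_pos])
    if (res$phi > PHI_TOL) {
      out[[length(out) + 1L]] <- list(
        mechanism = sys$units[mech_pos],
        phi = res$phi,
        cause = expand_repertoire(sys, res$cause$repertoire,
                                  match(res$cause$purview, sys$units), "cause"),
        effect = expand_repertoire(sys, res$effect$repertoire,
                                   match(res$effect$purview, sys$units), "effect"),
        cause_purview = res$cause$purview,
        effect_purview = res$effect$purview)
    }
  }
  out
}

concept_distance <- function(a, b, cost) {
  emd(a$cause, b$cause, cost) + emd(a$effect, b$effect, cost)
}

# extended EMD between two constellations: phi mass is transported between
# concepts; surplus mass on either side moves to/from the null concept
constellation_distance <- function(c0, c1, sys) {
  cost <- hamming_cost(sys$k)
  null <- null_concept(sys)
  m0 <- vapply(c0, `[[`, numeric(1), "phi")
  m1 <- vapply(c1, `[[`, numeric(1), "phi")
  supply <- c(m0, max(0, sum(m1) - sum(m0)))
  demand <- c(m1, max(0, sum(m0) - sum(m1)))
  all0 <- c(c0, list(null))
  all1 <- c(c1, list(null))
  C <- matrix(0, length(all0), length(all1))
  for (i in seq_along(all0)) {
    for (j in seq_along(all1)) {
      C[i, j] <- concept_distance(all0[[i]], all1[[j]], cost)
    }
  }
  keep0 <- supply > 1e-12
  keep1 <- demand > 1e-12
  if (!any(keep0) || !any(keep1)) return(0)
  min_cost_transport(supply[keep0], demand[keep1],
                     C[keep0, keep1, drop = FALSE])
}

# does any node in cols depend on any node in rows? (structural connectivity
# of the subsystem transition rule)
tpm_dependency <- function(tpm, k) {
  dep <- matrix(FALSE, k, k)
  states <- states_matrix(k)
  for (i in seq_len(k)) {
    lo <- which(states[, i] == 0L)
    hi <- lo + 2^(i - 1L)
    for (j in seq_len(k)) {
      dep[i, j] <- any(abs(tpm[lo, j] - tpm[hi, j]) > 1e-12)
    }
  }
  dep
}

# cut TPM: connections from part1 -> part2 are severed; inputs of part2
# nodes coming from part1 are marginalized uniformly
cut_tpm <- function(tpm, k, part1) {
  out <- tpm
  states <- states_matrix(k)
  n1 <- length(part1)
  subs <- states_matrix(n1)
  base_idx <- as.vector(states[, -part1, drop = FALSE] %*%
                          2^(setdiff(seq_len(k), part1) - 1L))
  for (j in setdiff(seq_len(k), part1)) {
    col <- numeric(2^k)
    # average over all replacements of the part1 bits
    for (s in seq_len(2^k)) {
      reps_idx <- base_idx[s] + as.vector(subs %*% 2^(part1 - 1L)) + 1L
      col[s] <- mean(tpm[reps_idx, j])
    }
    out[, j] <- col
  }
  out
}

#' Integrated information of a candidate system (big Phi)
#'
#' Computes the system's concepts (all mechanisms with small phi > 0) and
#' the minimal distance any unidirectional system cut imposes on that
#' conceptual structure. A cut severs the connections from one part to the
#' rest (severed inputs are noised by uniform marginalization); the distance
#' between the intact and the partitioned constellation is an extended earth
#' mover's distance transporting small-phi mass, with unmatched mass moved
#' to/from the null concept. Systems whose dependency structure already
#' contains a connection-free cut (feed-forward or disconnected systems)
#' have Phi = 0.
#'
#' @param system A `candidate_system` from [condition_tpm()].
#' @return A `phi_system` list: `phi`, `n_concepts`, `concepts` (tibble with
#'   mechanism, phi, purviews), and `min_cut`.
#' @examples
#' b <- markov_brain(arch_spec("smallbrain"), list())
#' big_phi(condition_tpm(b, 3:4, rep(0L, 6)))$phi
#' @export
big_phi <- function(system) {
  stopifnot(inherits(system, "candidate_system"))
  k <- system$k
  cons <- constellation(system)
  concepts_tbl <- if (length(cons) == 0L) {
    tibble(mechanism = character(0), phi = numeric(0),
           cause_purview = character(0), effect_purview = character(0))
  } else {
    purrr::map_dfr(cons, function(cc) {
      tibble(mechanism = paste(cc$mechanism, collapse = ","), phi = cc$phi,
             cause_purview = paste(cc$cause_purview, collapse = ","),
             effect_purview = paste(cc$effect_purview, collapse = ","))
    })
  }
  result <- function(phi, cut) {
    structure(list(phi = phi, n_concepts = length(cons),
                   concepts = concepts_tbl, min_cut = cut,
                   units = system$units, state = system$state),
              class = "phi_system")
  }
  if (length(cons) == 0L) {
    return(result(0, NULL))
  }
  if (k == 1L) {
    # a single unit cannot be partitioned into two parts; its integration is
    # its concept mass under the complete cut (all inputs noised)
    part1 <- 1L
    ctpm <- cut_tpm(system$tpm, k, part1)
    csys <- new_candidate_system(ctpm, system$units, system$state)
    d <- constellation_distance(cons, constellation(csys), system)
    return(result(d, system$units))
  }
  dep <- tpm_dependency(system$tpm, k)
  parts <- subsets_of(seq_len(k), 1L, k - 1L)
  # structural shortcut: a cut that severs no dependency leaves the system
  # unchanged
  for (part1 in parts) {
    part2 <- setdiff(seq_len(k), part1)
    if (!any(dep[part1, part2, drop = FALSE])) {
      return(result(0, system$units[part1]))
    }
  }
  best <- Inf
  best_cut <- NULL
  for (part1 in parts) {
    ctpm <- cut_tpm(system$tpm, k, part1)
    csys <- new_candidate_system(ctpm, system$units, system$state)
    d <- constellation_distance(cons, constellation(csys), system)
    if (d < best - PHI_TOL) {
      best <- d
      best_cut <- system$units[part1]
    }
    if (best < PHI_TOL) break
  }
  result(if (is.finite(best)) best else 0, best_cut)
}

#' @export
print.phi_system <- function(x, ...) {
  cat(sprintf("<phi_system> units {%s}, state %s: Phi = %.6g, %d concepts\n",
              paste(x$units, collapse = ","), paste(x$state, collapse = ""),
              x$phi, x$n_concepts))
  invisible(x)
}

#' Maximal integrated information over a lifetime
#'
#' For every distinct brain state visited during a trial, evaluates big Phi
#' for every candidate subset of computational units (memory and motors;
#' sensors are environment-clamped background) up to `max_units` units, and
#' returns the overall maximum with its subset and concept count. Brains
#' whose computational-unit count exceeds `hard_limit` are reported as not
#' computed rather than approximated.
#'
#' @param brain A [markov_brain()].
#' @param trial_log A `trial_log` whose `state` column records visited brain
#'   states.
#' @param max_units Largest candidate-subset size searched (exhaustive
#'   search; 5 is the practical exact-mode limit).
#' @param hard_limit Computational-unit count above which the result is
#'   `not computed`.
#' @return A `phi_result`: `phi_max`, `subset`, `state`, `n_concepts`,
#'   `computed`, and the per-state-per-subset table `details`.
#' @examples
#' w <- builtin_world("original")
#' b <- markov_brain(arch_spec("smallbrain"), list())
#' log <- run_trial(w, b, trial_config(group_size = 1, T = 3, seed = 1))
#' phi_max_over_lifetime(b, log, max_units = 2)$phi_max
#' @export
phi_max_over_lifetime <- function(brain, trial_log, max_units = 5L,
                                  hard_limit = 8L) {
  stopifnot(inherits(brain, "markov_brain"), inherits(trial_log, "trial_log"))
  ns <- brain$arch$n_sensors
  comp_units <- seq(ns + 1L, brain$n_units)
  if (length(comp_units) > hard_limit) {
    return(structure(list(phi_max = NA_real_, subset = NULL, state = NULL,
                          n_concepts = NA_integer_, computed = FALSE,
                          details = NULL),
                     class = "phi_result"))
  }
  visited <- unique(trial_log$state)
  visited <- visited[!is.na(visited)]
  if (length(visited) == 0L) stop_animats("trial log carries no brain states")
  subsets <- subsets_of(comp_units, 1L, min(max_units, length(comp_units)))
  details <- list()
  best <- list(phi = -Inf, subset = NULL, state = NULL, n_concepts = NA_integer_)
  for (st in visited) {
    for (su in subsets) {
      res <- big_phi(condition_tpm(brain, su, int_to_bits(st, brain$n_units),
                                   max_units = hard_limit))
      details[[length(details) + 1L]] <- tibble(
        state = st, subset = paste(su, collapse = ","), phi = res$phi,
        n_concepts = res$n_concepts)
      if (res$phi > best$phi + PHI_TOL) {
        best <- list(phi = res$phi, subset = su, state = st,
                     n_concepts = res$n_concepts)
      }
    }
  }
  structure(list(phi_max = max(best$phi, 0), subset = best$subset,
                 state = best$state, n_concepts = best$n_concepts,
                 computed = TRUE, details = dplyr::bind_rows(details)),
            class = "phi_result")
}

#' @export
print.phi_result <- function(x, ...) {
  if (!x$computed) {
    cat("<phi_result> not computed (brain exceeds the exact-mode size limit)\n")
  } else {
    cat(sprintf("<phi_result> Phi^Max = %.6g over units {%s} (state %d), %d concepts\n",
                x$phi_max, paste(x$subset, collapse = ","), x$state, x$n_concepts))
  }
  invisible(x)
}

#' @export
tidy.phi_result <- function(x, ...) {
  if (!x$computed) return(tibble())
  x$details
}

#' @export
glance.phi_result <- function(x, ...) {
  tibble(phi_max = x$phi_max,
         subset = paste(x$subset, collapse = ","),
         n_concepts = x$n_concepts, computed = x$computed)
}
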