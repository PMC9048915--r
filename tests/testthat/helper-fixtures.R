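# Shared fixtures built in code.

fine_grid <- function() seq(300, 700, by = 1)

# Noiseless sensitivity of a single-opsin cell on the measurement grid.
template_sens <- function(lambda_max, grid = default_grid(), ...) {
  spectral_sensitivity(grid, evaluate_template(
    pigment_template(lambda_max, ...), grid))
}

# Brute-force parsimony: minimum changes over all internal-state
# assignments of a rooted binary tree (independent of the Fitch pass).
brute_parsimony <- function(tree, tip_states) {
  st <- tip_states[tree$tip.label]
  ntip <- length(tree$tip.label)
  nnode <- tree$Nnode
  edge <- tree$edge
  grid <- as.matrix(expand.grid(rep(list(0:1), nnode)))
  best <- Inf
  for (r in seq_len(nrow(grid))) {
    states <- c(st, grid[r, ])
    # ambiguous tips: minimise over their states too
    amb <- which(is.na(states[seq_len(ntip)]))
    if (length(amb)) {
      sub <- as.matrix(expand.grid(rep(list(0:1), length(amb))))
      for (q in seq_len(nrow(sub))) {
        states[amb] <- sub[q, ]
        best <- min(best, sum(states[edge[, 1]] != states[edge[, 2]]))
      }
    } else {
      best <- min(best, sum(states[edge[, 1]] != states[edge[, 2]]))
    }
  }
  best
}

# Brute-force Mk likelihood: direct summation over internal assignments.
brute_mk_likelihood <- function(tree, tip_states, rate) {
  st <- tip_states[tree$tip.label]
  ntip <- length(tree$tip.label)
  nnode <- tree$Nnode
  edge <- tree$edge
  elen <- tree$edge.length
  pmat <- lapply(elen, function(t) {
    e <- exp(-2 * rate * t)
    matrix(c(0.5 + 0.5 * e, 0.5 - 0.5 * e, 0.5 - 0.5 * e, 0.5 + 0.5 * e), 2)
  })
  root <- ntip + 1L
  total <- 0
  grid <- as.matrix(expand.grid(rep(list(0:1), nnode)))
  for (r in seq_len(nrow(grid))) {
    states <- c(st, grid[r, ])
    lik <- 0.5  # uniform root prior
    ok <- TRUE
    for (i in seq_len(nrow(edge))) {
      sp <- states[edge[i, 1]]; sc <- states[edge[i, 2]]
      if (is.na(sc)) { # ambiguous tip: sum both states
        lik <- lik * sum(pmat[[i]][sp + 1, ])
      } else {
        lik <- lik * pmat[[i]][sp + 1, sc + 1]
      }
      if (!ok) break
    }
    total <- total + lik
  }
  total
}

packaged_tree <- function()
  ape::read.tree(system.file("extdata", "heliconiini_blue_opsin.nwk",
                             package = "rhodofit"))

packaged_states <- function()
  read_character_table(system.file("extdata", "ser116ala_states.csv",
                                   package = "rhodofit"))
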