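#' Initialize the network-formation simulation
#'
#' Sets up the spatiotemporally nonexplicit individual-based model. At
#' initialization each dyad receives a fixed association probability drawn
#' from the triangular distribution of its (kinship tier, age pair) entry;
#' each core group receives a within-group context probability
#' (`within_context_prob`, default 1, i.e. ungated) and each pair of core
#' groups a between-group context probability drawn from its tier's
#' triangular entry for a matriarch-matriarch pair (the matriarchs standing
#' for their groups). Probabilities are drawn once and held fixed for the
#' whole run; interaction counts start at zero.
#'
#' @param pop Population roster.
#' @param table Association-probability table covering every (tier, age
#'   pair) present in the population.
#' @param seed Optional integer seed.
#' @param within_context_prob Probability that a core group's within-group
#'   context is "on" at a time step (scalar in `[0, 1]`; default 1 leaves
#'   within-group association driven purely by the dyad probabilities).
#' @return A list of class `"sim_state"` with elements `pop`, `dyads`
#'   (dyad table with fixed probability `p` and context index), `contexts`
#'   (context probabilities), `counts` (per-dyad tallies) and `t`.
#' @export
initialize_simulation <- function(pop, table = default_probability_table(),
                                  seed = NULL, within_context_prob = 1) {
  pop <- validate_population(pop)
  table <- validate_probability_table(table)
  if (within_context_prob < 0 || within_context_prob > 1) {
    abort("`within_context_prob` must be in [0, 1].")
  }

  with_seed_if(seed, {
    dy <- dyad_table(pop)
    ent <- lookup_probability(table, dy$tier, dy$age_a, dy$age_b)
    dy$p <- rtriangular(nrow(dy), ent$min, ent$mode, ent$max)

    gp <- group_pair_tier(pop)
    if (nrow(gp)) {
      gent <- lookup_probability(table, gp$tier, "matriarch", "matriarch")
      gp$p <- rtriangular(nrow(gp), gent$min, gent$mode, gent$max)
    } else {
      gp$p <- numeric(0)
    }

    cores <- sort(unique(pop$core_id))
    contexts <- bind_rows(
      tibble(context = cores, p = within_context_prob),
      tibble(context = pair_key(gp$group_a, gp$group_b), p = gp$p)
    )
    dy$context_idx <- match(
      ifelse(dy$tier == "core", dy$core_a, pair_key(dy$core_a, dy$core_b)),
      contexts$context
    )

    structure(
      list(
        pop = pop,
        dyads = dy,
        contexts = contexts,
        counts = integer(nrow(dy)),
        t = 0L
      ),
      class = "sim_state"
    )
  })
}

#' Advance the simulation by one time step
#'
#' At each time step one uniform random number is drawn per context (core
#' group or group pair): the context is on iff its probability exceeds the
#' draw. For every dyad whose context is on, a second uniform draw decides
#' association: the dyad associates iff its fixed probability exceeds the
#' draw, and its interaction count increments by exactly one.
#'
#' @param state A `"sim_state"` from [initialize_simulation()].
#' @return The updated state (counts and `t` advanced). Uses the current
#'   RNG stream; seed the run as a whole (see [simulate_network()]).
#' @export
simulation_step <- function(state) {
  stopifnot(inherits(state, "sim_state"))
  ctx_on <- state$contexts$p > stats::runif(nrow(state$contexts))
  active <- ctx_on[state$dyads$context_idx]
  assoc <- active & (state$dyads$p > stats::runif(nrow(state$dyads)))
  state$counts <- state$counts + as.integer(assoc)
  state$t <- state$t + 1L
  state
}

#' Simulate network formation in a virtual population
#'
#' Runs the individual-based model for `n_steps` time steps and captures
#' snapshot networks (interaction counts as edge weights; zero-count dyads
#' omitted) at the requested steps, recording the network density (fraction
#' of dyads with at least one interaction) of each snapshot.
#'
#' @inheritParams initialize_simulation
#' @param n_steps Total number of time steps (>= 1).
#' @param snapshot_at Increasing vector of steps in `[1, n_steps]` at which
#'   to capture snapshots.
#' @param id Identifier prefix for the snapshot networks.
#' @param normalize If `TRUE`, divide snapshot weights by the elapsed time
#'   steps, mapping them to `[0, 1]` for qualitative comparison with
#'   association-index networks. Default keeps raw integer counts.
#' @return A tibble with one row per snapshot: `t`, `density`, `network`
#'   (list column of [assoc_network()] objects).
#' @examples
#' pop <- generate_population(population_config(1, 1, 2), seed = 1)
#' sims <- simulate_network(pop, n_steps = 50, snapshot_at = c(25, 50), seed = 9)
#' @export
simulate_network <- function(pop, table = default_probability_table(),
                             n_steps = 500,
                             snapshot_at = seq(100, 500, by = 100),
                             seed = NULL, within_context_prob = 1,
                             id = "sim", normalize = FALSE) {
  stopifnot_scalar_count(n_steps, "n_steps", min = 1)
  snapshot_at <- sort(unique(as.integer(snapshot_at)))
  if (any(snapshot_at < 1 | snapshot_at > n_steps)) {
    abort("`snapshot_at` must lie within [1, n_steps].")
  }

  with_seed_if(seed, {
    state <- initialize_simulation(pop, table,
                                   within_context_prob = within_context_prob)
    out <- vector("list", length(snapshot_at))
    k <- 1L
    for (t in seq_len(n_steps)) {
      state <- simulation_step(state)
      if (k <= length(snapshot_at) && t == snapshot_at[k]) {
        out[[k]] <- snapshot_network(state, sprintf("%s_t%d", id, t), normalize)
        k <- k + 1L
      }
    }
    tibble(
      t = snapshot_at,
      density = purrr::map_dbl(out, network_density),
      network = out
    )
  })
}

snapshot_network <- function(state, id, normalize = FALSE) {
  keep <- state$counts > 0
  w <- state$counts[keep]
  if (normalize) w <- w / state$t
  assoc_network(
    tibble(
      id_a = state$dyads$id_a[keep],
      id_b = state$dyads$id_b[keep],
      weight = w
    ),
    roster = state$pop,
    id = id
  )
}
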