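#' Configuration for virtual population generation
#'
#' Describes the multi-tier composition of a virtual elephant population:
#' how many clans, how bond groups are spread over clans, how core groups
#' are spread over bond groups, and the age profile of each core group.
#'
#' The default composition mirrors the scale of the reference free-ranging
#' population: 3 clans holding 4, 3 and 1 bond groups, and 10 core groups
#' spread over the 8 bonds. Each core group holds exactly one matriarch plus
#' counts of young, prime and mature adults drawn from bounded integer
#' distributions with the stated means (young: mean 2 on \[1, 5\]; prime:
#' mean 2 on \[0, 7\]; mature: mean 1 on \[0, 3\]).
#'
#' @param n_clans Number of clans (>= 1).
#' @param bonds_per_clan Integer vector of length `n_clans` (or a scalar,
#'   recycled) giving the number of bond groups in each clan.
#' @param cores_per_bond Integer vector of length `sum(bonds_per_clan)` (or a
#'   scalar, recycled) giving the number of core groups in each bond group.
#' @param age_profile Tibble with columns `age_category`, `min`, `max`,
#'   `mean` defining the bounded integer sampler for the number of
#'   individuals of each category per core group. The mean must lie in
#'   `[min, max]`.
#' @return A list of class `"population_config"`.
#' @seealso [generate_population()]
#' @examples
#' cfg <- population_config(n_clans = 1, bonds_per_clan = 1, cores_per_bond = 1)
#' @export
population_config <- function(n_clans = 3,
                              bonds_per_clan = c(4, 3, 1),
                              cores_per_bond = c(1, 1, 2, 1, 2, 1, 1, 1),
                              age_profile = default_age_profile()) {
  stopifnot_scalar_count(n_clans, "n_clans", min = 1)
  bonds_per_clan <- rep_len(as.integer(bonds_per_clan), n_clans)
  if (any(bonds_per_clan < 1)) abort("Every clan must contain at least one bond group.")
  n_bonds <- sum(bonds_per_clan)
  cores_per_bond <- rep_len(as.integer(cores_per_bond), n_bonds)
  if (any(cores_per_bond < 1)) abort("Every bond group must contain at least one core group.")

  required <- c("age_category", "min", "max", "mean")
  if (!all(required %in% names(age_profile))) {
    abort("`age_profile` needs columns age_category, min, max, mean.")
  }
  if (!setequal(age_profile$age_category, age_levels())) {
    abort("`age_profile` must cover exactly the four age categories.")
  }
  bad <- age_profile$mean < age_profile$min | age_profile$mean > age_profile$max |
    age_profile$min > age_profile$max
  if (any(bad)) {
    abort(sprintf(
      "Invalid age profile (mean outside [min, max]) for: %s",
      paste(age_profile$age_category[bad], collapse = ", ")
    ))
  }

  structure(
    list(
      n_clans = as.integer(n_clans),
      bonds_per_clan = bonds_per_clan,
      cores_per_bond = cores_per_bond,
      age_profile = as_tibble(age_profile)
    ),
    class = "population_config"
  )
}

#' @rdname population_config
#' @export
default_age_profile <- function() {
  tibble(
    age_category = age_levels(),
    min  = c(1, 0, 0, 1),
    max  = c(5, 7, 3, 1),
    mean = c(2, 2, 1, 1)
  )
}

# Bounded integer sampler on [min, max] with expectation exactly `mean`:
# min + Binomial(max - min, (mean - min)/(max - min)). Degenerate bounds give
# the constant. Unimodal, respects the printed bounds, and the mean is exact.
draw_age_count <- function(n, min, max, mean) {
  if (max == min) return(rep.int(as.integer(min), n))
  as.integer(min) + stats::rbinom(n, size = max - min, prob = (mean - min) / (max - min))
}

#' Generate a virtual multi-tier population
#'
#' Draws a static population of adult females arranged in nested core, bond
#' and clan groups. Every core group receives exactly one matriarch; the
#' number of young, prime and mature adults is drawn independently per core
#' group from the bounded integer samplers in the configuration.
#'
#' @param config A [population_config()].
#' @param seed Optional integer seed; the same seed reproduces the population
#'   exactly. `NULL` uses (and advances) the current RNG stream.
#' @return A population roster: tibble with columns `id`, `age_category`,
#'   `core_id`, `bond_id`, `clan_id`.
#' @examples
#' pop <- generate_population(population_config(), seed = 1)
#' dplyr::count(pop, core_id)
#' @export
generate_population <- function(config = population_config(), seed = NULL) {
  if (!inherits(config, "population_config")) {
    abort("`config` must be created by population_config().")
  }
  with_seed_if(seed, {
    bond_clan <- rep(seq_len(config$n_clans), config$bonds_per_clan)
    core_bond <- rep(seq_along(config$cores_per_bond), config$cores_per_bond)
    n_cores <- length(core_bond)

    prof <- config$age_profile
    rows <- vector("list", n_cores)
    for (g in seq_len(n_cores)) {
      counts <- vapply(seq_len(nrow(prof)), function(k) {
        draw_age_count(1L, prof$min[k], prof$max[k], prof$mean[k])
      }, integer(1))
      cat_vec <- rep(prof$age_category, counts)
      rows[[g]] <- tibble(
        age_category = cat_vec,
        core_id = sprintf("C%02d", g),
        bond_id = sprintf("B%d", core_bond[g]),
        clan_id = sprintf("K%d", bond_clan[core_bond[g]])
      )
    }
    out <- bind_rows(rows)
    out <- mutate(out,
      id = sprintf("%s_%02d", .data$core_id, stats::ave(
        rep(1L, nrow(out)), out$core_id, FUN = seq_along
      ))
    )
    validate_population(select(
      out, "id", "age_category", "core_id", "bond_id", "clan_id"
    ))
  })
}

#' Validate a population roster
#'
#' Checks the structural invariants of a multi-tier roster: unique ids,
#' known age categories, exactly one matriarch and at least two members per
#' core group, and strict nesting (each core group in one bond group, each
#' bond group in one clan).
#'
#' @param pop Population roster tibble (see [generate_population()]).
#' @return `pop`, invisibly unchanged, as a tibble.
#' @export
validate_population <- function(pop) {
  pop <- as_tibble(pop)
  required <- c("id", "age_category", "core_id", "bond_id", "clan_id")
  missing <- setdiff(required, names(pop))
  if (length(missing)) {
    abort(sprintf("Roster is missing columns: %s", paste(missing, collapse = ", ")))
  }
  if (anyDuplicated(pop$id)) abort("Roster ids must be unique.")
  age_rank(pop$age_category) # errors on unknown labels

  per_core <- pop |>
    group_by(.data$core_id) |>
    summarise(
      n = n(),
      n_matriarch = sum(.data$age_category == "matriarch"),
      n_bond = n_distinct(.data$bond_id),
      .groups = "drop"
    )
  if (any(per_core$n_matriarch != 1L)) {
    abort("Every core group must contain exactly one matriarch.")
  }
  if (any(per_core$n < 2L)) abort("Every core group must have at least two members.")
  if (any(per_core$n_bond != 1L)) abort("Each core group must belong to exactly one bond group.")
  per_bond <- pop |>
    group_by(.data$bond_id) |>
    summarise(n_clan = n_distinct(.data$clan_id), .groups = "drop")
  if (any(per_bond$n_clan != 1L)) abort("Each bond group must belong to exactly one clan.")
  pop
}

#' The Amboseli reference population
#'
#' Returns the fixed multi-tier structure of the 10 free-ranging core groups
#' used as the empirical template: core groups AA (10 individuals), CB (6),
#' DB (4), EA (9), EB (10), FB (6), JAYA (8), GB (11), OA (10) and PC (9) --
#' 83 females in total -- aggregated into eight bond groups (B1 = AA;
#' B2 = FB; B3 = EA + EB; B4 = DB; B5 = CB + OA; B6 = GB; B7 = PC;
#' B8 = JAYA) and three clans (K1 = B1-B4, K2 = B5-B7, K3 = B8).
#'
#' Individual ages are not published, so age categories are assigned by a
#' seeded draw: each core group gets one matriarch, and the remaining
#' members receive young/prime/mature counts drawn from the default bounded
#' samplers conditioned on the core-group size (rejection sampling). The
#' group structure is fixed; only the age assignment depends on `seed`.
#'
#' @param seed Integer seed for the synthetic age-category assignment.
#' @return A population roster tibble (see [generate_population()]).
#' @examples
#' amb <- amboseli_population()
#' nrow(amb) # 83
#' @export
amboseli_population <- function(seed = 1) {
  sizes <- c(
    AA = 10, CB = 6, DB = 4, EA = 9, EB = 10,
    FB = 6, JAYA = 8, GB = 11, OA = 10, PC = 9
  )
  bonds <- c(
    AA = "B1", FB = "B2", EA = "B3", EB = "B3", DB = "B4",
    CB = "B5", OA = "B5", GB = "B6", PC = "B7", JAYA = "B8"
  )
  clans <- c(
    B1 = "K1", B2 = "K1", B3 = "K1", B4 = "K1",
    B5 = "K2", B6 = "K2", B7 = "K2", B8 = "K3"
  )
  prof <- default_age_profile()
  non_mat <- prof[prof$age_category != "matriarch", ]

  with_seed_if(seed, {
    rows <- lapply(names(sizes), function(core) {
      n_rest <- sizes[[core]] - 1L
      # rejection-sample bounded counts conditioned on the core-group size
      for (attempt in seq_len(10000L)) {
        counts <- vapply(seq_len(nrow(non_mat)), function(k) {
          draw_age_count(1L, non_mat$min[k], non_mat$max[k], non_mat$mean[k])
        }, integer(1))
        if (sum(counts) == n_rest) break
        if (attempt == 10000L) abort("Could not match core-group size to age bounds.")
      }
      cats <- c("matriarch", rep(non_mat$age_category, counts))
      tibble(
        id = sprintf("%s_%02d", core, seq_along(cats)),
        age_category = cats,
        core_id = core,
        bond_id = bonds[[core]],
        clan_id = clans[[bonds[[core]]]]
      )
    })
    validate_population(bind_rows(rows))
  })
}
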