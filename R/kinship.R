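#' Kinship tier of a dyad
#'
#' Classifies pairs of individuals by the innermost social tier they share:
#' `"core"` (same core group, close kin), `"bond"` (same bond group,
#' different core groups; intermediate kin), `"clan"` (same clan, different
#' bond groups; distant kin) or `"nonkin"` (different clans).
#'
#' @param core_a,core_b,bond_a,bond_b,clan_a,clan_b Group memberships of the
#'   two individuals (vectorized).
#' @return Character vector of tiers.
#' @examples
#' kinship_tier("C1", "C1", "B1", "B1", "K1", "K1") # "core"
#' @export
kinship_tier <- function(core_a, core_b, bond_a, bond_b, clan_a, clan_b) {
  dplyr::case_when(
    core_a == core_b ~ "core",
    bond_a == bond_b ~ "bond",
    clan_a == clan_b ~ "clan",
    TRUE ~ "nonkin"
  )
}

kinship_levels <- function() c("core", "bond", "clan", "nonkin")

#' All dyads of a population with tier and age-pair labels
#'
#' Enumerates every unordered pair of individuals in a roster, attaching the
#' kinship tier and the canonical age-pair label (younger category first,
#' e.g. `"Y-G"`). This is the bookkeeping table behind the network-formation
#' simulator and the weak-link census.
#'
#' @param pop Population roster (see [generate_population()]).
#' @return Tibble with columns `id_a`, `id_b`, `age_a`, `age_b`, `core_a`,
#'   `core_b`, `tier`, `age_pair`.
#' @export
dyad_table <- function(pop) {
  pop <- validate_population(pop)
  n <- nrow(pop)
  if (n < 2) abort("Need at least two individuals to form dyads.")
  idx <- utils::combn(n, 2)
  a <- idx[1, ]
  b <- idx[2, ]
  tibble(
    id_a = pop$id[a],
    id_b = pop$id[b],
    age_a = pop$age_category[a],
    age_b = pop$age_category[b],
    core_a = pop$core_id[a],
    core_b = pop$core_id[b],
    tier = kinship_tier(
      pop$core_id[a], pop$core_id[b],
      pop$bond_id[a], pop$bond_id[b],
      pop$clan_id[a], pop$clan_id[b]
    ),
    age_pair = age_pair_label(pop$age_category[a], pop$age_category[b])
  )
}

# tier shared by two *core groups* (never "core"): bond / clan / nonkin
group_pair_tier <- function(pop) {
  groups <- pop |>
    distinct(.data$core_id, .data$bond_id, .data$clan_id)
  if (nrow(groups) < 2) {
    return(tibble(
      group_a = character(), group_b = character(), tier = character()
    ))
  }
  idx <- utils::combn(nrow(groups), 2)
  a <- idx[1, ]
  b <- idx[2, ]
  tibble(
    group_a = groups$core_id[a],
    group_b = groups$core_id[b],
    tier = dplyr::case_when(
      groups$bond_id[a] == groups$bond_id[b] ~ "bond",
      groups$clan_id[a] == groups$clan_id[b] ~ "clan",
      TRUE ~ "nonkin"
    )
  )
}
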