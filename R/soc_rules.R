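#' Describe the character of an electronic state
#'
#' Captures the qualitative features that the one-center Slater-Condon
#' analysis of spin-orbit coupling needs: the excitation type and whether
#' the orbitals an electron leaves/enters carry a strong admixture of a
#' heavy-atom valence p orbital, with its orientation relative to the
#' molecular plane.
#'
#' @param character One of `"ground_closed_shell"`, `"pi_pi_star"`,
#'   `"n_pi_star"`, `"pi_sigma_star"`, `"n_sigma_star"`.
#' @param source_heavy_p Does the source orbital have strong heavy-atom p
#'   admixture?
#' @param source_orientation `"in_plane"` or `"out_of_plane"` (only
#'   meaningful when `source_heavy_p`).
#' @param target_heavy_p,target_orientation Same for the target orbital.
#' @param same_heavy_atom Are the key orbitals located on one heavy atom?
#'   Default TRUE (single dominant heavy substituent).
#' @return A list of class `state_character`.
#' @export
state_character <- function(character,
                            source_heavy_p = FALSE, source_orientation = NA,
                            target_heavy_p = FALSE, target_orientation = NA,
                            same_heavy_atom = TRUE) {
  allowed <- c("ground_closed_shell", "pi_pi_star", "n_pi_star",
               "pi_sigma_star", "n_sigma_star")
  if (!character %in% allowed)
    stop("unknown character label: ", character,
         " (expected one of ", paste(allowed, collapse = ", "), ")")
  if (!is.na(source_orientation) &&
      !source_orientation %in% c("in_plane", "out_of_plane"))
    stop("source_orientation must be in_plane or out_of_plane")
  if (!is.na(target_orientation) &&
      !target_orientation %in% c("in_plane", "out_of_plane"))
    stop("target_orientation must be in_plane or out_of_plane")
  structure(list(character = character,
                 source_heavy_p = isTRUE(source_heavy_p),
                 source_orientation = source_orientation,
                 target_heavy_p = isTRUE(target_heavy_p),
                 target_orientation = target_orientation,
                 same_heavy_atom = isTRUE(same_heavy_atom)),
            class = "state_character")
}

soc_categories <- list(
  units            = c(1, 9),
  tens             = c(10, 99),
  hundreds_to_2000 = c(100, 2000),
  atomic_like_2300 = c(2200, 2400)
)

#' Qualitative spin-orbit coupling magnitude between two state characters
#'
#' Implements the one-center Slater-Condon selection rule for heavy
#' main-group substituents: SOC between a singlet and a triplet is large
#' only when the two states differ in a single pair of MOs that each carry a
#' strong admixture of a DIFFERENT (hence mutually perpendicular) valence p
#' orbital of the SAME heavy atom. Same p orientation, differences in two or
#' more MO pairs, or near-identical occupations all suppress the coupling.
#' The classifier is a transparent rule table with a human-readable
#' rationale; it computes no integrals and is intended for designing
#' realistic model-system SOC magnitudes and annotating hop-character
#' reports. The commonly quoted El-Sayed rules are the special case of this
#' analysis for states differing in orbital type.
#'
#' Category anchors (cm^-1): `units` (single digits, e.g. between pi-pi*
#' states), `tens` (moderate, e.g. closed shell vs n-pi*),
#' `hundreds_to_2000` (large, e.g. closed shell vs pi-sigma* with an
#' out-of-plane heavy p in the pi orbital), `atomic_like_2300` (the atomic
#' limit, closed shell vs n-sigma* with both MOs essentially atomic).
#'
#' Classification is symmetric in its arguments and total over the five
#' character labels.
#'
#' @param a,b [state_character()] descriptors; one singlet-type, one
#'   triplet-type by the caller's bookkeeping.
#' @return A list of class `soc_category`: `label`, `representative_range`
#'   (cm^-1 pair) and `rationale`.
#' @examples
#' classify_soc_pair(
#'   state_character("ground_closed_shell"),
#'   state_character("n_sigma_star", source_heavy_p = TRUE,
#'                   source_orientation = "in_plane",
#'                   target_heavy_p = TRUE, target_orientation = "in_plane")
#' )$label  # "atomic_like_2300"
#' @export
classify_soc_pair <- function(a, b) {
  stopifnot(inherits(a, "state_character"), inherits(b, "state_character"))
  key <- sort(c(a$character, b$character))
  same_atom <- a$same_heavy_atom && b$same_heavy_atom
  pick <- function(label, why) {
    structure(list(label = label,
                   representative_range = soc_categories[[label]],
                   rationale = why),
              class = "soc_category")
  }
  ## identical characters: near-identical occupation numbers suppress SOC
  if (key[1] == key[2])
    return(pick("units", paste0("states of the same ", key[1], " character have ",
                                "nearly the same orbital occupations; SOC suppressed")))
  k <- paste(key, collapse = "|")
  ## helper: the excited member of a pair involving the closed-shell ground state
  other <- if (a$character == "ground_closed_shell") b else a
  switch(
    k,
    "ground_closed_shell|n_sigma_star" = pick(
      "atomic_like_2300",
      paste0("single MO pair (n -> sigma*), both essentially atomic p of the same ",
             "heavy atom and mutually perpendicular: atomic-limit SOC (~2300 cm^-1)")),
    "ground_closed_shell|pi_sigma_star" =
      if (other$source_heavy_p &&
          identical(other$source_orientation, "out_of_plane") && same_atom)
        pick("hundreds_to_2000",
             paste0("single MO pair (pi -> sigma*); pi has strong out-of-plane heavy-atom ",
                    "p admixture perpendicular to the in-plane sigma* p: large SOC"))
      else
        pick("units",
             "pi lacks heavy-atom p admixture (or different atoms): one-center integrals vanish"),
    "ground_closed_shell|n_pi_star" = pick(
      "tens",
      paste0("single MO pair (n -> pi*), but the pi* target can have at best weak ",
             "heavy-atom p admixture: moderate SOC (tens of cm^-1)")),
    "ground_closed_shell|pi_pi_star" = pick(
      "units",
      paste0("even with heavy-atom admixture in both MOs it is the SAME out-of-plane ",
             "p orbital: SOC in units of cm^-1")),
    "n_sigma_star|pi_sigma_star" =
      if ((a$source_heavy_p || b$source_heavy_p) && same_atom)
        pick("hundreds_to_2000",
             paste0("states share sigma*, differ in (n vs pi) source with perpendicular ",
                    "p admixtures of the same heavy atom: large SOC"))
      else
        pick("tens", "shared sigma* but weak/absent heavy-atom p in the pi source; moderate, text-derived"),
    "n_pi_star|n_sigma_star" = pick(
      "tens",
      paste0("states share the n source, differ in (pi* vs sigma*) targets; pi* carries ",
             "at best weak heavy-atom p: moderate SOC")),
    "n_pi_star|pi_pi_star" =
      if ((a$source_heavy_p || b$source_heavy_p) && same_atom)
        pick("hundreds_to_2000",
             paste0("same pi* target, (n vs pi) sources with perpendicular p admixtures ",
                    "of the same heavy atom: large SOC (El-Sayed-type)"))
      else
        pick("units", "sources lack same-atom heavy p admixture: differ effectively in > 1 MO pair"),
    "pi_pi_star|pi_sigma_star" = pick(
      "tens",
      paste0("shared source pi assumed; targets (pi* vs sigma*) with weak pi* heavy-p ",
             "admixture: moderate, text-derived")),
    "n_sigma_star|pi_pi_star" = pick(
      "units", "states differ in at least two MO pairs: SOC quite small"),
    "n_pi_star|pi_sigma_star" = pick(
      "units", "states differ in at least two MO pairs: SOC quite small"),
    stop("unhandled character pair: ", k)
  )
}

#' @export
print.soc_category <- function(x, ...) {
  cat("<soc_category> ", x$label, " (",
      x$representative_range[1], "-", x$representative_range[2], " cm^-1)\n  ",
      x$rationale, "\n", sep = "")
  invisible(x)
}
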