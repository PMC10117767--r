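.new_partition <- function(retained, recoverable, lost) {
  fr <- c(retained = retained, recoverable = recoverable, lost = lost)
  if (any(fr < -1e-12) || any(fr > 1 + 1e-12)) {
    stop("partition fractions must lie in [0, 1]; got retained=",
         signif(retained, 4), ", recoverable=", signif(recoverable, 4),
         ", lost=", signif(lost, 4), call. = FALSE)
  }
  structure(
    list(retained_fraction = retained,
         recoverable_fraction = recoverable,
         lost_fraction = lost,
         basis = "fed nitrogen"),
    class = "nue_partition"
  )
}

#' Nitrogen partition for a manure-based animal system
#'
#' Splits fed nitrogen into retained (the protein conversion efficiency),
#' recoverable (plant-available manure N corrected for volatilization
#' during direct injection and for leaching), and lost (the remainder).
#' Recoverable N is `available x volatilization_retention x
#' (1 - leaching_loss)`; the two corrections commute, so their order does
#' not matter numerically.
#'
#' @param pce protein conversion efficiency (retained fraction).
#' @param available_n_fraction plant-available manure N as a fraction of
#'   fed N, before corrections.
#' @param volatilization_retention fraction surviving volatilization
#'   (0.98 for direct injection).
#' @param leaching_loss fraction lost to leaching (0.20).
#' @return A `nue_partition`: retained, recoverable, and lost fractions
#'   summing to 1.
#' @export
animal_partition <- function(pce, available_n_fraction,
                             volatilization_retention = 0.98,
                             leaching_loss = 0.20) {
  for (x in c(pce, available_n_fraction, volatilization_retention,
              leaching_loss)) {
    if (x < 0 || x > 1) stop("inputs must lie in [0, 1]", call. = FALSE)
  }
  recoverable <- available_n_fraction * volatilization_retention *
    (1 - leaching_loss)
  .new_partition(pce, recoverable, 1 - pce - recoverable)
}

#' Nitrogen partition for cultured meat
#'
#' Without recovery technology all non-retained nitrogen in the spent
#' media is lost: retained equals the PCE, recoverable equals the chosen
#' recovery fraction of fed N (0 by default), and lost is the remainder.
#'
#' @param pce protein conversion efficiency.
#' @param recovery_fraction_of_fed fraction of fed N recovered from the
#'   spent media, default 0.
#' @return A `nue_partition`.
#' @export
cm_partition <- function(pce, recovery_fraction_of_fed = 0) {
  if (pce < 0 || pce > 1 || recovery_fraction_of_fed < 0) {
    stop("inputs must lie in [0, 1]", call. = FALSE)
  }
  .new_partition(pce, recovery_fraction_of_fed,
                 1 - pce - recovery_fraction_of_fed)
}

#' Spent-media nitrogen recovery rate needed for parity
#'
#' How much nitrogen a cultured-meat facility must recover to match a
#' target system's lost fraction: the difference between the no-recovery
#' lost fraction and the target, expressed both as a fraction of fed N
#' and as a fraction of the waste stream.
#'
#' @param cm_lost_no_recovery cultured-meat lost fraction without
#'   recovery.
#' @param target_lost the comparator system's lost fraction; must not
#'   exceed `cm_lost_no_recovery`.
#' @return list: `fed_basis`, `waste_basis` (fractions).
#' @export
recovery_to_match <- function(cm_lost_no_recovery, target_lost) {
  if (target_lost > cm_lost_no_recovery) {
    stop("target lost fraction exceeds the current waste fraction",
         call. = FALSE)
  }
  fed <- cm_lost_no_recovery - target_lost
  list(fed_basis = fed, waste_basis = fed / cm_lost_no_recovery)
}

#' Person-equivalents of an annual nitrogen load
#'
#' Expresses a waste nitrogen mass as the number of people excreting the
#' same nitrogen annually (13 g N per person per day by default).
#'
#' @param annual_n kg N per year.
#' @param excretion g N per person per day, > 0.
#' @return persons.
#' @examples
#' person_equivalents(36500)  # ~7,700
#' @export
person_equivalents <- function(annual_n,
                               excretion =
                                 cm_constants()$person_n_excretion_g_day) {
  if (excretion <= 0) stop("excretion must be > 0", call. = FALSE)
  annual_n / (excretion * cm_constants()$days_per_year / 1000)
}

#' Nitrogen-use-efficiency comparison table
#'
#' Retained / recoverable / lost partitions of fed nitrogen for each
#' conventional system and for cultured meat without recovery, plus the
#' recovery rates (fed and waste basis) cultured meat would need to match
#' each animal system whose lost fraction is lower.
#'
#' @param scenario output of [load_scenario()].
#' @param cm_recovery recovery fraction of fed N for the cultured-meat
#'   column, default 0.
#' @return list with `partitions` (data frame: system, retained,
#'   recoverable, lost) and `parity` (data frame: target system, required
#'   recovery fed-basis and waste-basis; `NA` where cultured meat already
#'   loses less).
#' @export
nue_table <- function(scenario = load_scenario(), cm_recovery = 0) {
  parts <- lapply(names(scenario$animals), function(sp) {
    a <- scenario$animals[[sp]]
    gm <- feed_and_protein(a)
    p <- animal_partition(gm$pce, a$manure_available_n_fraction)
    data.frame(system = sp,
               retained = p$retained_fraction,
               recoverable = p$recoverable_fraction,
               lost = p$lost_fraction,
               stringsAsFactors = FALSE)
  })
  cmp <- cm_partition(scenario$cm_batch$protein_conversion_efficiency,
                      cm_recovery)
  parts <- c(parts, list(data.frame(
    system = "cultured meat",
    retained = cmp$retained_fraction,
    recoverable = cmp$recoverable_fraction,
    lost = cmp$lost_fraction,
    stringsAsFactors = FALSE
  )))
  partitions <- do.call(rbind, parts)
  rownames(partitions) <- NULL

  cm_lost <- cm_partition(
    scenario$cm_batch$protein_conversion_efficiency, 0)$lost_fraction
  parity <- do.call(rbind, lapply(names(scenario$animals), function(sp) {
    tl <- partitions$lost[partitions$system == sp]
    if (tl <= cm_lost) {
      r <- recovery_to_match(cm_lost, tl)
      data.frame(target = sp, recovery_fed_basis = r$fed_basis,
                 recovery_waste_basis = r$waste_basis,
                 stringsAsFactors = FALSE)
    } else {
      data.frame(target = sp, recovery_fed_basis = NA_real_,
                 recovery_waste_basis = NA_real_, stringsAsFactors = FALSE)
    }
  }))
  rownames(parity) <- NULL
  list(partitions = partitions, parity = parity)
}
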