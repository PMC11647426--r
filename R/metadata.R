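DRUGS <- c("saline", "SCH23390", "haloperidol")

#' Session metadata for one animal / open-field session
#'
#' @param animal_id Opaque animal identifier (coerced to character).
#' @param drug One of `"saline"`, `"SCH23390"`, `"haloperidol"`.
#' @param dose Dose in mg/kg; must be 0 for saline.
#' @param test_round Open-field exposure number for this animal (1-4).
#' @param quadrant Arena quadrant the animal was placed in (1-4).
#' @param sex `"F"` or `"M"`.
#' @param slot Start timeslot, `"0900"` or `"1200"`.
#' @return An object of class `session_metadata`.
#' @export
session_metadata <- function(animal_id, drug = "saline", dose = 0,
                             test_round = 1L, quadrant = 1L,
                             sex = "F", slot = "0900") {
  drug <- match.arg(drug, DRUGS)
  stopifnot(is.numeric(dose), length(dose) == 1L, dose >= 0)
  if (drug == "saline" && dose != 0)
    stop("saline sessions must have dose = 0", call. = FALSE)
  if (drug != "saline" && dose <= 0)
    stop("antagonist sessions must have dose > 0", call. = FALSE)
  test_round <- as.integer(test_round)
  quadrant <- as.integer(quadrant)
  if (is.na(test_round) || test_round < 1L || test_round > 4L)
    stop("test_round must be in 1..4 (at most four injections per animal)",
         call. = FALSE)
  if (is.na(quadrant) || quadrant < 1L || quadrant > 4L)
    stop("quadrant must be in 1..4", call. = FALSE)
  sex <- match.arg(sex, c("F", "M"))
  slot <- match.arg(as.character(slot), c("0900", "1200"))
  structure(
    list(animal_id = as.character(animal_id), drug = drug, dose = dose,
         test_round = test_round, quadrant = quadrant, sex = sex, slot = slot),
    class = "session_metadata")
}

#' @export
print.session_metadata <- function(x, ...) {
  cat(sprintf("<session_metadata> animal %s | %s %g mg/kg | round %d | quadrant %d | %s | slot %s\n",
              x$animal_id, x$drug, x$dose, x$test_round, x$quadrant, x$sex, x$slot))
  invisible(x)
}

meta_to_list <- function(meta) {
  unclass(meta)
}

meta_from_list <- function(lst) {
  session_metadata(animal_id = lst$animal_id, drug = lst$drug,
                   dose = as.numeric(lst$dose),
                   test_round = as.integer(lst$test_round),
                   quadrant = as.integer(lst$quadrant),
                   sex = lst$sex, slot = lst$slot)
}
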