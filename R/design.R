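#' Lattice dosing design for an open-field cohort
#'
#' Animals are tested in batches of four (one per arena quadrant,
#' simultaneously).  In every batch exactly one animal receives saline and
#' the other three receive antagonist doses; the saline role rotates within
#' the batch across rounds.  No animal ever receives the same (drug, dose)
#' combination twice, each animal is injected at most four times, and
#' consecutive rounds are scheduled seven simulated days apart (satisfying
#' the five-day washout).  Treatment combinations are drawn from a balanced
#' pool so dose groups end up with comparable round and quadrant
#' distributions.
#'
#' @param n_animals Number of animals; must be divisible by 4.
#' @param doses Named list of per-drug dose vectors (mg/kg).  The default is
#'   the five-dose grid per compound used for the dose-response study.
#' @param n_rounds Number of test rounds (1-4).
#' @param seed Integer seed fixing the randomized assignment.
#' @return A `design_plan`: a `data.frame` with one row per
#'   (animal, assignment) and columns `animal_id, batch, test_round, day,
#'   slot, quadrant, drug, dose`.
#' @export
make_lattice_design <- function(n_animals,
                                doses = list(
                                  SCH23390 = c(0.005, 0.01, 0.02, 0.05, 0.5),
                                  haloperidol = c(0.05, 0.1, 0.2, 0.5, 1)),
                                n_rounds = 4, seed = 1) {
  if (n_animals %% 4 != 0)
    stop("n_animals must be divisible by 4 (batches of four)", call. = FALSE)
  n_rounds <- as.integer(n_rounds)
  if (n_rounds < 1L || n_rounds > 4L)
    stop("n_rounds must be in 1..4 (at most four injections per animal)",
         call. = FALSE)
  bad <- names(doses)[!names(doses) %in% setdiff(DRUGS, "saline")]
  if (length(bad))
    stop("unknown drug(s) in dose list: ", paste(bad, collapse = ", "),
         call. = FALSE)
  combos <- do.call(rbind, lapply(names(doses), function(d) {
    if (any(doses[[d]] <= 0)) stop("doses must be > 0", call. = FALSE)
    data.frame(drug = d, dose = doses[[d]])
  }))
  n_combos <- nrow(combos)
  n_batches <- n_animals / 4L
  slots_total <- 3L * n_batches * n_rounds
  if (slots_total < n_combos)
    stop("infeasible design: ", n_combos, " (drug, dose) combinations but only ",
         slots_total, " treatment slots; add animals or rounds", call. = FALSE)
  if (n_rounds - 1L > n_combos)
    stop("infeasible design: an animal would need more distinct treatments than exist",
         call. = FALSE)

  with_seed(seed, {
    animal_id <- sprintf("A%03d", seq_len(n_animals))
    batch <- rep(seq_len(n_batches), each = 4L)
    pos <- rep(1:4, n_batches)   # position within batch

    rows <- vector("list", n_rounds)
    # balanced treatment pool over all rounds, shuffled
    pool <- combos[sample(rep(seq_len(n_combos),
                              length.out = slots_total)), , drop = FALSE]
    pool_i <- 1L
    used <- vector("list", n_animals)  # combos already given to each animal

    for (r in seq_len(n_rounds)) {
      saline_pos <- ((r - 1L) %% 4L) + 1L
      quadrant <- ((pos + r - 2L) %% 4L) + 1L
      slot <- ifelse((batch + r) %% 2L == 0L, "0900", "1200")
      drug <- character(n_animals); dose <- numeric(n_animals)
      for (a in seq_len(n_animals)) {
        if (pos[a] == saline_pos) {
          drug[a] <- "saline"; dose[a] <- 0
        } else {
          key <- function(k) paste(pool$drug[k], pool$dose[k])
          # take the next pool entry this animal has not had yet
          take <- pool_i
          probe <- 0L
          while (key(take) %in% used[[a]]) {
            probe <- probe + 1L
            take <- (pool_i + probe - 1L) %% nrow(pool) + 1L
            if (probe > nrow(pool))
              stop("could not satisfy no-repeat constraint; use a different seed",
                   call. = FALSE)
          }
          drug[a] <- pool$drug[take]; dose[a] <- pool$dose[take]
          used[[a]] <- c(used[[a]], key(take))
          # swap consumed entry to current head so the pool stays a multiset
          pool[c(pool_i, take), ] <- pool[c(take, pool_i), ]
          pool_i <- pool_i %% nrow(pool) + 1L
        }
      }
      rows[[r]] <- data.frame(
        animal_id = animal_id, batch = batch, test_round = r,
        day = (r - 1L) * 7L + 1L, slot = slot, quadrant = quadrant,
        drug = drug, dose = dose, stringsAsFactors = FALSE)
    }
    plan <- do.call(rbind, rows)
    rownames(plan) <- NULL
    class(plan) <- c("design_plan", "data.frame")
    validate_design(plan)
    plan
  })
}

#' Validate the invariants of a design plan
#'
#' Checks: exactly one saline animal per (batch, round); at most four
#' assignments per animal; no repeated (drug, dose) per animal; at least five
#' days between an animal's assignments; saline implies dose 0.
#'
#' @param plan A `design_plan`.
#' @return `plan`, invisibly; stops on violation.
#' @export
validate_design <- function(plan) {
  stopifnot(is.data.frame(plan))
  sal <- plan$drug == "saline"
  if (any(plan$dose[sal] != 0)) stop("saline rows must have dose 0", call. = FALSE)
  per_batch <- tapply(sal, interaction(plan$batch, plan$test_round, drop = TRUE), sum)
  if (any(per_batch != 1L))
    stop("each batch must contain exactly one saline animal per round", call. = FALSE)
  n_per_animal <- table(plan$animal_id)
  if (any(n_per_animal > 4L))
    stop("an animal may receive at most four injections", call. = FALSE)
  combo <- paste(plan$animal_id, plan$drug, plan$dose)
  combo <- combo[!sal]
  if (anyDuplicated(combo))
    stop("an animal received the same (drug, dose) twice", call. = FALSE)
  gaps <- tapply(plan$day, plan$animal_id, function(d) diff(sort(d)))
  if (any(unlist(gaps) < 5))
    stop("assignments of one animal must be at least five days apart", call. = FALSE)
  invisible(plan)
}
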