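#' Sample-size scenarios
#'
#' A scenario fixes the number of hospitals sampled per type stratum; all
#' strategies keep the 1:1:1 stratum ratio. The three named scenarios are
#' `"A"` (4 per stratum, 12 in total), `"B"` (6 per stratum, 18) and `"C"`
#' (2 per stratum, 6).
#'
#' @param x Either a scenario name (`"A"`, `"B"`, `"C"`) or a named integer
#'   vector over `academic`/`teaching`/`general`, or a single integer applied
#'   to every stratum.
#' @return Named integer vector of per-stratum sample sizes, class `scenario`.
#' @examples
#' scenario("A")
#' scenario(c(academic = 2, teaching = 5, general = 5))
#' @export
scenario <- function(x = "A") {
  if (inherits(x, "scenario")) return(x)
  if (is.character(x) && length(x) == 1) {
    n <- switch(toupper(x), A = 4L, B = 6L, C = 2L,
                stop_config("unknown scenario name '", x, "' (use A, B or C)"))
    x <- rep(n, 3)
    names(x) <- HOSPITAL_TYPES
  } else if (is.numeric(x) && length(x) == 1) {
    x <- rep(as.integer(x), 3)
    names(x) <- HOSPITAL_TYPES
  } else if (is.numeric(x) && !is.null(names(x))) {
    x <- x[HOSPITAL_TYPES]
    names(x) <- HOSPITAL_TYPES
  } else {
    stop_config("scenario must be a name or a named per-stratum vector")
  }
  if (anyNA(x) || any(x < 1)) stop_config("per-stratum sample sizes must all be >= 1")
  structure(as.integer(x), names = HOSPITAL_TYPES, class = "scenario")
}

#' @export
print.scenario <- function(x, ...) {
  cat("Scenario:", paste(sprintf("%s=%d", names(x), x), collapse = ", "),
      sprintf("(total %d)\n", sum(x)))
  invisible(x)
}

check_feasible <- function(pop, scen) {
  sizes <- table(factor(pop$type, levels = HOSPITAL_TYPES))
  for (ty in HOSPITAL_TYPES) {
    if (scen[ty] > sizes[ty]) {
      stop_infeasible("infeasible scenario: ", scen[ty], " hospitals requested from the '",
                      ty, "' stratum which holds only ", sizes[ty])
    }
  }
  invisible(TRUE)
}

new_selection <- function(strategy, ids, region_pair = NULL,
                          replicate_index = 1L, shortfall = 0L) {
  structure(list(strategy = strategy,
                 hospital_ids = ids,
                 region_pair = region_pair,
                 replicate_index = as.integer(replicate_index),
                 shortfall = as.integer(shortfall)),
            class = "selection")
}

#' @export
print.selection <- function(x, ...) {
  cat(sprintf("Selection [%s]: %d hospitals", toupper(x$strategy),
              length(x$hospital_ids)))
  if (!is.null(x$region_pair)) {
    cat(" from regions", paste(x$region_pair, collapse = " + "))
  }
  if (x$shortfall > 0) cat(sprintf(" (shortfall %d)", x$shortfall))
  cat("\n  ", paste(x$hospital_ids, collapse = ", "), "\n")
  invisible(x)
}

stratum_rows <- function(pop, ty) which(pop$type == ty)

#' Largest-hospitals sampling (LARG)
#'
#' Per stratum, the `n` hospitals with the most beds. Purely deterministic;
#' ties in bed count break by ascending hospital id.
#'
#' @param pop A `hospital_population`.
#' @param scen A [scenario()].
#' @return A `selection`.
#' @family sampling strategies
#' @export
select_largest <- function(pop, scen = scenario("A")) {
  scen <- scenario(scen)
  check_feasible(pop, scen)
  ids <- unlist(lapply(HOSPITAL_TYPES, function(ty) {
    i <- stratum_rows(pop, ty)
    i <- i[order(-pop$beds[i], pop$hospital_id[i])]
    pop$hospital_id[i[seq_len(scen[ty])]]
  }))
  new_selection("larg", ids)
}

#' Maximum-variation sampling (MAXVAR)
#'
#' Per stratum, the hospitals at both extremes of red-cell (`rbc`) use:
#' `ceiling(n/2)` with the highest counts and `floor(n/2)` with the lowest
#' (the extra seat for odd `n` goes to the high end by default). Selection is
#' keyed on `rbc` only; deterministic, ties break by ascending id.
#'
#' @inheritParams select_largest
#' @param high_end_extra For odd per-stratum `n`, give the extra seat to the
#'   high end (`TRUE`, default) or the low end.
#' @return A `selection`.
#' @family sampling strategies
#' @export
select_maxvar <- function(pop, scen = scenario("A"), high_end_extra = TRUE) {
  scen <- scenario(scen)
  check_feasible(pop, scen)
  ids <- unlist(lapply(HOSPITAL_TYPES, function(ty) {
    i <- stratum_rows(pop, ty)
    n <- scen[ty]
    n_hi <- if (high_end_extra) ceiling(n / 2) else floor(n / 2)
    n_lo <- n - n_hi
    hi <- i[order(-pop$rbc[i], pop$hospital_id[i])][seq_len(n_hi)]
    rest <- setdiff(i, hi)
    lo <- rest[order(pop$rbc[rest], pop$hospital_id[rest])][seq_len(n_lo)]
    pop$hospital_id[c(hi, lo)]
  }))
  new_selection("maxvar", ids)
}

#' Stratified simple random sampling (RAND)
#'
#' Per stratum, a simple random sample without replacement of size `n`; every
#' hospital in a stratum has inclusion probability `n/N`. Uses the current R
#' random stream; seed with [set.seed()] (or [derive_seed()]) to reproduce.
#'
#' @inheritParams select_largest
#' @return A `selection`.
#' @family sampling strategies
#' @export
select_random <- function(pop, scen = scenario("A")) {
  scen <- scenario(scen)
  check_feasible(pop, scen)
  ids <- unlist(lapply(HOSPITAL_TYPES, function(ty) {
    i <- stratum_rows(pop, ty)
    pop$hospital_id[i[sample.int(length(i), scen[ty])]]
  }))
  new_selection("rand", ids)
}

#' Regional-variation sampling (REGVAR)
#'
#' Per stratum, maximizes the number of regions represented: the regions that
#' contain at least one hospital of the stratum are randomly permuted and
#' seats are filled round-robin over that permutation, drawing one uniformly
#' random not-yet-selected hospital from each region per pass until `n` are
#' chosen. The number of distinct regions represented therefore always equals
#' `min(n, number of occupied regions)`.
#'
#' @inheritParams select_largest
#' @return A `selection`.
#' @family sampling strategies
#' @export
select_regvar <- function(pop, scen = scenario("A")) {
  scen <- scenario(scen)
  check_feasible(pop, scen)
  ids <- unlist(lapply(HOSPITAL_TYPES, function(ty) {
    i <- stratum_rows(pop, ty)
    n <- scen[ty]
    occupied <- unique(pop$region[i])
    perm <- if (length(occupied) > 1) sample(occupied) else occupied
    chosen <- integer(0)
    while (length(chosen) < n) {
      for (r in perm) {
        if (length(chosen) >= n) break
        avail <- setdiff(i[pop$region[i] == r], chosen)
        if (length(avail)) {
          chosen <- c(chosen, avail[sample.int(length(avail), 1)])
        }
      }
    }
    pop$hospital_id[chosen]
  }))
  new_selection("regvar", ids)
}

#' Enumerate all unordered pairs of regions
#'
#' @param regions Character vector of at least two region labels.
#' @return A two-column character matrix, one row per unordered pair, rows
#'   and columns in lexicographic order. Seven regions give 21 pairs.
#' @examples
#' nrow(enumerate_region_pairs(paste0("R", 1:7)))
#' @export
enumerate_region_pairs <- function(regions) {
  regions <- sort(unique(as.character(regions)))
  if (length(regions) < 2) stop_config("need at least 2 regions to form pairs")
  t(utils::combn(regions, 2))
}

#' Two-region sampling (2REG)
#'
#' Samples (nearly) all hospitals from two organizational regions. The
#' academic stratum takes every academic centre located in the pair — two by
#' construction of the region layout, three when the dual-academic region is
#' in the pair — regardless of the scenario. For the teaching and general
#' strata the scenario's `n` is split evenly across the two regions (for odd
#' `n` the extra seat goes to a uniformly random member of the pair); within
#' a region hospitals are drawn uniformly without replacement; if a region
#' holds fewer hospitals of the stratum than its share, all of them are taken
#' and the unfilled seats move to the other region; if the pair jointly holds
#' fewer than `n`, all are taken and the shortfall is recorded on the
#' selection.
#'
#' @inheritParams select_largest
#' @param pair Character vector of two distinct region labels.
#' @return A `selection` with `region_pair` and `shortfall` filled in.
#' @family sampling strategies
#' @export
select_two_regions <- function(pop, scen = scenario("A"), pair) {
  scen <- scenario(scen)
  regions <- attr(pop, "regions")
  if (length(pair) != 2 || pair[1] == pair[2]) {
    stop_config("pair must hold two distinct region labels")
  }
  missing_r <- setdiff(pair, regions)
  if (length(missing_r)) {
    stop_config("region label(s) not in the population: ",
                paste(missing_r, collapse = ", "))
  }
  shortfall <- 0L
  acad <- stratum_rows(pop, "academic")
  ids <- pop$hospital_id[acad[pop$region[acad] %in% pair]]
  for (ty in c("teaching", "general")) {
    i <- stratum_rows(pop, ty)
    n <- scen[ty]
    in1 <- i[pop$region[i] == pair[1]]
    in2 <- i[pop$region[i] == pair[2]]
    q1 <- n %/% 2
    q2 <- n %/% 2
    if (n %% 2 == 1) {
      if (sample.int(2, 1) == 1) q1 <- q1 + 1L else q2 <- q2 + 1L
    }
    take1 <- min(q1, length(in1))
    take2 <- min(q2, length(in2))
    # seats a region cannot fill move to the other region
    spare <- n - take1 - take2
    if (spare > 0) {
      extra1 <- min(spare, length(in1) - take1)
      take1 <- take1 + extra1
      take2 <- take2 + min(spare - extra1, length(in2) - take2)
    }
    sel1 <- if (take1 > 0) in1[sample.int(length(in1), take1)] else integer(0)
    sel2 <- if (take2 > 0) in2[sample.int(length(in2), take2)] else integer(0)
    shortfall <- shortfall + (n - take1 - take2)
    ids <- c(ids, pop$hospital_id[c(sel1, sel2)])
  }
  new_selection("2reg", ids, region_pair = sort(pair), shortfall = shortfall)
}

#' Draw a selection with any of the five strategies
#'
#' Dispatch helper used by the simulation driver: for `"2reg"` a region pair
#' is first drawn uniformly from [enumerate_region_pairs()] unless one is
#' supplied.
#'
#' @inheritParams select_largest
#' @param strategy One of `"larg"`, `"maxvar"`, `"rand"`, `"regvar"`, `"2reg"`.
#' @param pair Optional region pair for `"2reg"`.
#' @return A `selection`.
#' @export
draw_selection <- function(pop, strategy, scen = scenario("A"), pair = NULL) {
  strategy <- match.arg(tolower(strategy), STRATEGIES)
  switch(strategy,
         larg = select_largest(pop, scen),
         maxvar = select_maxvar(pop, scen),
         rand = select_random(pop, scen),
         regvar = select_regvar(pop, scen),
         "2reg" = {
           if (is.null(pair)) {
             pairs <- enumerate_region_pairs(attr(pop, "regions"))
             pair <- pairs[sample.int(nrow(pairs), 1), ]
           }
           select_two_regions(pop, scen, pair)
         })
}
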