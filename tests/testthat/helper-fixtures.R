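# Small hand-built populations used across the strategy and inference tests.

# One 6-hospital stratum of each type with known beds and rbc counts:
# beds 50..300 step 50, rbc 10,40,90,160,250,360 (ids A..F within stratum).
toy_population <- function(regions = c("r1", "r1", "r2", "r3", "r2", "r3")) {
  one <- function(ty, prefix) {
    data.frame(hospital_id = paste0(prefix, LETTERS[1:6]),
               type = ty, region = regions,
               beds = seq(50, 300, by = 50),
               rbc = c(10, 40, 90, 160, 250, 360),
               ffp = c(5, 20, 45, 80, 125, 180),
               plt = c(2, 8, 18, 32, 50, 72),
               stringsAsFactors = FALSE)
  }
  as_population(rbind(one("academic", "a"), one("teaching", "t"),
                      one("general", "g")),
                regions = c("r1", "r2", "r3"))
}

# random feasible population for property-style fuzzing
fuzz_population <- function(seed) {
  sizes <- c(academic = sample(4:9, 1), teaching = sample(6:20, 1),
             general = sample(8:30, 1))
  generate_population(generator_config(stratum_sizes = sizes,
                                       n_regions = sample(3:8, 1),
                                       dual_academic_region = "R1",
                                       seed = seed))
}

ids_in_stratum <- function(pop, sel, ty) {
  sum(pop$type[match(sel$hospital_ids, pop$hospital_id)] == ty)
}
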