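#' Simulate the monitored population
#'
#' Each site-year yields one territorial pair (a male and a female). A
#' recruitment category (0 / F / M / MF: which pair member is newly settled)
#' is drawn per event from the configured frequencies; a recruited member
#' gets a fresh identity with experience 1, otherwise experience increments
#' (capped at 15 years). Initial occupants start with 1-8 years on site.
#'
#' @param config a `cpf_sim_config`.
#' @return list with `individuals` (individual_id, sex, site_id,
#'   first_year), `events` (site_id, year, male_id, female_id,
#'   male_experience, female_experience, recruitment) and `nests`
#'   (site_id, lat, lon).
#' @export
simulate_population <- function(config) {
  stopifnot(inherits(config, "cpf_sim_config"))
  set.seed(substream_seed(config$seed, 2))
  n_sites <- config$n_sites
  years <- config$first_year + seq_len(config$n_years) - 1

  nests <- config$nest_coords
  if (is.null(nests)) {
    nests <- data.frame(
      site_id = sprintf("site%02d", seq_len(max(n_sites, 1))),
      lat = stats::runif(max(n_sites, 1), 43.3, 44.3),
      lon = stats::runif(max(n_sites, 1), 3.3, 4.7),
      stringsAsFactors = FALSE
    )[seq_len(n_sites), , drop = FALSE]
  }
  if (n_sites == 0) {
    empty_ind <- data.frame(individual_id = character(), sex = character(),
                            site_id = character(), first_year = integer(),
                            stringsAsFactors = FALSE)
    empty_ev <- data.frame(site_id = character(), year = integer(),
                           male_id = character(), female_id = character(),
                           male_experience = integer(),
                           female_experience = integer(),
                           recruitment = character(), stringsAsFactors = FALSE)
    return(list(individuals = empty_ind, events = empty_ev,
                nests = nests[0, , drop = FALSE]))
  }

  lv <- names(config$recruitment_freqs)
  counter <- 0
  new_id <- function(sex) {
    counter <<- counter + 1
    sprintf("%s%04d", tolower(sex), counter)
  }
  individuals <- list(); events <- list()
  for (s in seq_len(n_sites)) {
    site <- nests$site_id[s]
    cur <- list(
      M = list(id = new_id("M"), exp = sample(1:8, 1), first = years[1]),
      F = list(id = new_id("F"), exp = sample(1:8, 1), first = years[1])
    )
    individuals[[length(individuals) + 1]] <- data.frame(
      individual_id = c(cur$M$id, cur$F$id), sex = c("M", "F"),
      site_id = site, first_year = years[1], stringsAsFactors = FALSE)
    for (y in years) {
      if (y > years[1]) {
        rec <- sample(lv, 1, prob = config$recruitment_freqs)
        for (sx in c("M", "F")) {
          if (grepl(sx, rec, fixed = TRUE)) {
            cur[[sx]] <- list(id = new_id(sx), exp = 1, first = y)
            individuals[[length(individuals) + 1]] <- data.frame(
              individual_id = cur[[sx]]$id, sex = sx, site_id = site,
              first_year = y, stringsAsFactors = FALSE)
          } else {
            cur[[sx]]$exp <- min(cur[[sx]]$exp + 1, 15)
          }
        }
      } else {
        # first monitored year can itself be a recruitment year
        rec <- sample(lv, 1, prob = config$recruitment_freqs)
        for (sx in c("M", "F")) {
          if (grepl(sx, rec, fixed = TRUE)) cur[[sx]]$exp <- 1
        }
      }
      events[[length(events) + 1]] <- data.frame(
        site_id = site, year = y,
        male_id = cur$M$id, female_id = cur$F$id,
        male_experience = cur$M$exp, female_experience = cur$F$exp,
        recruitment = rec, stringsAsFactors = FALSE)
    }
  }
  list(individuals = do.call(rbind, individuals),
       events = do.call(rbind, events),
       nests = nests)
}
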