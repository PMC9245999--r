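#' Configuration for the stepwise-mutation-model simulator
#'
#' The simulator emulates the structure a forensic Y-STR population study
#' assumes: an ancestral founder haplotype, one founder per population
#' diverging from it for `t_split` time units, and independent sampled
#' lineages diverging from their population founder for `t_within` units.
#' Mutations follow the symmetric single-step model: the number of
#' mutations on a lineage segment of length `t` at a locus with rate `mu`
#' is Poisson(`mu * t`), each step changing the repeat count by +1 or -1
#' with equal probability.
#'
#' Default rates and depths are in arbitrary time units scaled so that
#' `mu * t = 0.5` expected mutations per locus per lineage segment —
#' moderate diversity comparable to what slowly/moderately mutating
#' forensic panels show within continental populations.
#'
#' @param panel a [ystr_panel()] (default: the bundled 30-copy panel).
#' @param populations data frame with columns `id`, `n` (males sampled)
#'   and optionally `haplogroup` (founder clade label, defaults to the
#'   population id).
#' @param mu per-locus mutation rate per time unit; scalar or one value
#'   per panel row (a dual-copy locus applies its rate to each copy
#'   independently).
#' @param t_within expected time depth from the population founder to
#'   each sampled lineage.
#' @param t_split time from the ancestral founder to each population
#'   founder.
#' @param founder_alleles ancestral repeat count(s); scalar or one per
#'   panel row.
#' @param microvariant_prob probability that a simulated call acquires a
#'   partial-repeat (".2") designation, exercising microvariant parsing
#'   and scoring paths.
#' @param seed integer seed; the whole table is reproducible from it.
#' @return a `sim_config` list.
#' @export
sim_config <- function(panel = agcu_y30_panel(),
                       populations = data.frame(id = c("popA", "popB"),
                                                n = c(50L, 50L)),
                       mu = 0.05, t_within = 10, t_split = 10,
                       founder_alleles = 13L, microvariant_prob = 0,
                       seed = 1L) {
  stopifnot(inherits(panel, "ystr_panel"))
  populations <- as.data.frame(populations, stringsAsFactors = FALSE)
  if (!all(c("id", "n") %in% colnames(populations))) {
    stop("populations needs columns id, n", call. = FALSE)
  }
  if (!"haplogroup" %in% colnames(populations)) {
    populations$haplogroup <- populations$id
  }
  if (any(populations$n < 1L)) stop("sample sizes must be >= 1",
                                    call. = FALSE)
  if (anyDuplicated(populations$id)) stop("population ids must be unique",
                                          call. = FALSE)
  mu <- rep_len(as.numeric(mu), nrow(panel))
  founder_alleles <- rep_len(as.integer(founder_alleles), nrow(panel))
  if (any(mu < 0) || t_within < 0 || t_split < 0) {
    stop("rates and times must be nonnegative", call. = FALSE)
  }
  if (microvariant_prob < 0 || microvariant_prob > 1) {
    stop("microvariant_prob must be in [0, 1]", call. = FALSE)
  }
  structure(list(panel = panel, populations = populations, mu = mu,
                 t_within = t_within, t_split = t_split,
                 founder_alleles = founder_alleles,
                 microvariant_prob = microvariant_prob,
                 seed = as.integer(seed)),
            class = "sim_config")
}

# one SMM step burst: value + sum of Poisson(lambda) signed unit steps,
# floored at 1 repeat (biological lower bound)
.smm_mutate <- function(values, lambda) {
  k <- stats::rpois(length(values), lambda)
  steps <- vapply(k, function(ki) {
    if (ki == 0L) 0L else sum(sample(c(-1L, 1L), ki, replace = TRUE))
  }, integer(1))
  pmax(1L, values + steps)
}

#' Simulate a haplotype table under the stepwise mutation model
#'
#' Forward star-genealogy simulation: each population founder is the
#' ancestral haplotype after Poisson(`mu * t_split`) signed unit steps
#' per locus copy; each sampled male is his population founder after
#' Poisson(`mu * t_within`) further steps. Dual-copy loci are simulated
#' as two independent copies and canonicalized. Under this model the
#' expected squared repeat distance between two lineages separated by
#' total time `T` is `2 * mu * T` per locus, giving the closed-form
#' expectations reported in the truth object.
#'
#' @param config a [sim_config()].
#' @return list with `table` (a `haplotype_table` carrying population and
#'   haplogroup labels in `provenance` and a `Haplogroup` attribute) and
#'   `truth`: founders per population, `d_within`/`d_between` (expected
#'   squared distances over the single-copy loci, the default distance
#'   set) and `rst_expected ~ t_split / (t_split + t_within)`.
#' @export
simulate_table <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  panel <- config$panel
  copies <- .panel_copies(panel)
  mu_copy <- config$mu[copies$row]
  founder_copy <- config$founder_alleles[copies$row]
  pops <- config$populations
  founders <- matrix(NA_integer_, nrow(pops), nrow(copies),
                     dimnames = list(pops$id, NULL))
  rows <- list()
  sample_ids <- character(0)
  pop_ids <- character(0)
  hg_ids <- character(0)
  for (p in seq_len(nrow(pops))) {
    founders[p, ] <- .smm_mutate(founder_copy, mu_copy * config$t_split)
    for (s in seq_len(pops$n[p])) {
      vals <- .smm_mutate(founders[p, ], mu_copy * config$t_within)
      frac <- integer(length(vals))
      if (config$microvariant_prob > 0) {
        hit <- stats::runif(length(vals)) < config$microvariant_prob
        frac[hit] <- 2L
      }
      rows[[length(rows) + 1L]] <- list(vals = vals, frac = frac)
      sample_ids <- c(sample_ids, sprintf("%s_%03d", pops$id[p], s))
      pop_ids <- c(pop_ids, pops$id[p])
      hg_ids <- c(hg_ids, pops$haplogroup[p])
    }
  }
  # render copies into canonical locus cells
  cells <- matrix("", length(rows), nrow(panel),
                  dimnames = list(NULL, panel$name))
  for (r in seq_along(rows)) {
    desig <- mapply(function(v, f) {
      if (f > 0L) paste0(v, ".", f) else as.character(v)
    }, rows[[r]]$vals, rows[[r]]$frac)
    for (i in seq_len(nrow(panel))) {
      idx <- which(copies$row == i)
      cells[r, i] <- paste(desig[idx][order(allele_score(desig[idx]))],
                           collapse = ",")
    }
  }
  tab <- haplotype_table(panel, sample_ids, cells, population_id = pop_ids,
                         provenance = sprintf("simulated seed=%d",
                                              config$seed))
  attr(tab, "haplogroup") <- hg_ids
  single <- panel$copy_number == 1L
  mu_single <- config$mu[single]
  truth <- list(
    founders = founders,
    d_within = 2 * sum(mu_single) * config$t_within,
    d_between = 2 * sum(mu_single) * (config$t_within + config$t_split),
    rst_expected = if (config$t_split + config$t_within > 0) {
      config$t_split / (config$t_split + config$t_within)
    } else 0
  )
  list(table = tab, truth = truth)
}

#' Simulate a labeled haplogroup reference panel
#'
#' One founder per haplogroup (the `populations` rows of the config are
#' read as haplogroup founders), `records_per_haplogroup` labeled records
#' each, simulated exactly as [simulate_table()].
#'
#' @param config a [sim_config()] with >= 2 populations/haplogroups.
#' @param records_per_haplogroup records simulated per haplogroup.
#' @param locus_overlap_min passed to [reference_panel()].
#' @return a [reference_panel()] whose labels are the simulation truth.
#' @export
simulate_reference_panel <- function(config, records_per_haplogroup = 10L,
                                     locus_overlap_min = 10L) {
  stopifnot(inherits(config, "sim_config"))
  if (nrow(config$populations) < 2L) {
    stop("need at least 2 haplogroup founders", call. = FALSE)
  }
  cfg <- config
  cfg$populations$n <- rep(as.integer(records_per_haplogroup),
                           nrow(cfg$populations))
  sim <- simulate_table(cfg)
  reference_panel(sim$table, attr(sim$table, "haplogroup"),
                  locus_overlap_min)
}
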