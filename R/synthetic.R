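#' Simulate a network with planted seed modules and bridge drivers
#'
#' Builds a test bed emulating the two-disease expansion scenario: an
#' Erdős–Rényi background graph plus two internally wired seed modules (one
#' per disease) and one or more "driver" hubs connected to the genes of both
#' modules. The module genes double as the two diseases' seed sets and as
#' the ground-truth common-gene construction, so a correct key-driver scan
#' must rank the planted hubs first. Driver hubs receive no background
#' edges, keeping their neighborhoods exactly the planted module genes.
#'
#' All randomness flows through `seed` (via [withr::with_seed]), so
#' regeneration with the same seed and parameters is identical.
#'
#' @param n_genes total number of genes before isolated-gene pruning.
#' @param p_background Erdős–Rényi edge probability among non-driver genes.
#' @param module_sizes integer vector of length 2: sizes of the two planted
#'   seed modules.
#' @param driver_degree number of module genes each driver is wired to
#'   (split as evenly as possible between the two modules); cannot exceed
#'   `sum(module_sizes)`.
#' @param n_drivers number of planted driver hubs.
#' @param p_module edge probability inside each module, on top of a ring
#'   that keeps the module connected.
#' @param seed integer random seed.
#' @return object of class `planted_network`: list with `network` (a
#'   [ppi_network()]), `seeds_a`, `seeds_b`, `drivers`, `params`, `seed`.
#' @export
simulate_network <- function(n_genes = 200, p_background = 0.02,
                             module_sizes = c(15, 15),
                             driver_degree = sum(module_sizes),
                             n_drivers = 1, p_module = 0.3, seed = 1L) {
  stopifnot(length(module_sizes) == 2L, all(module_sizes >= 3),
            n_drivers >= 1, p_background >= 0, p_background <= 1)
  if (n_genes < sum(module_sizes) + n_drivers + 2L) {
    stop("`n_genes` too small for the requested modules and drivers",
         call. = FALSE)
  }
  if (driver_degree > sum(module_sizes)) {
    stop("`driver_degree` exceeds the number of module genes; infeasible",
         call. = FALSE)
  }
  genes <- sprintf("G%04d", seq_len(n_genes))
  ia <- seq_len(module_sizes[1L])
  ib <- module_sizes[1L] + seq_len(module_sizes[2L])
  idr <- sum(module_sizes) + seq_len(n_drivers)
  rest <- setdiff(seq_len(n_genes), c(ia, ib, idr))

  ring <- function(idx) cbind(idx, c(idx[-1L], idx[1L]))
  er_pairs <- function(idx, p) {
    if (length(idx) < 2L || p <= 0) return(matrix(integer(), ncol = 2L))
    cmb <- utils::combn(idx, 2L)
    keep <- stats::runif(ncol(cmb)) < p
    t(cmb[, keep, drop = FALSE])
  }
  withr::with_seed(seed, {
    em <- rbind(ring(ia), ring(ib), er_pairs(ia, p_module),
                er_pairs(ib, p_module))
    # each driver: wired to driver_degree module genes, alternating modules
    edrv <- do.call(rbind, lapply(idr, function(dr) {
      na <- min(module_sizes[1L], ceiling(driver_degree / 2))
      nb <- driver_degree - na
      tgt <- c(sample(ia, na), sample(ib, nb))
      cbind(dr, tgt)
    }))
    # background among non-driver genes
    ebg <- er_pairs(c(ia, ib, rest), p_background)
    ed <- rbind(em, edrv, ebg)
  })
  edges <- data.frame(gene_a = genes[ed[, 1L]], gene_b = genes[ed[, 2L]],
                      score = 0.95, stringsAsFactors = FALSE)
  net <- ppi_network(edges, score_threshold = 0.9)
  structure(
    list(network = net,
         seeds_a = intersect(genes[ia], net$genes),
         seeds_b = intersect(genes[ib], net$genes),
         drivers = intersect(genes[idr], net$genes),
         params = list(n_genes = n_genes, p_background = p_background,
                       module_sizes = module_sizes,
                       driver_degree = driver_degree,
                       n_drivers = n_drivers, p_module = p_module),
         seed = seed),
    class = "planted_network")
}

#' Simulate a set of case-control genotype studies
#'
#' Draws `k` studies around a true present-genotype log odds ratio `theta`
#' with between-study variance `tau2`: each study's log OR is
#' `theta_i ~ Normal(theta, tau2)`, the control present-genotype prevalence
#' is `p0`, the case prevalence follows from the odds-ratio relation
#' `p1 = OR p0 / (1 - p0 + OR p0)`, and the present-genotype counts are
#' binomial draws at the study's arm sizes. Studies whose draw produces an
#' empty table margin are redrawn (capped at 100 attempts).
#'
#' Defaults mirror the scale of published GSTM1 hepatotoxicity study sets:
#' 14 studies, true OR 0.71, tau2 0.05, control present prevalence 0.57,
#' and arm-size ranges spanning the published case (17-104) and control
#' (33-391) totals.
#'
#' @param k number of studies.
#' @param theta true log odds ratio (present vs null genotype).
#' @param tau2 between-study variance of the log OR, >= 0.
#' @param p0 control present-genotype prevalence, in (0, 1).
#' @param n_cases,n_controls per-study arm sizes: either a length-2 range
#'   sampled uniformly, or a length-`k` vector used as-is.
#' @param seed integer random seed.
#' @return object of class `meta_sim`: list with `studies` (a
#'   `genotype_studies` table), `theta`, `tau2`, `p0`, `seed`.
#' @export
simulate_meta_studies <- function(k = 14, theta = log(0.71), tau2 = 0.05,
                                  p0 = 0.57, n_cases = c(17, 104),
                                  n_controls = c(33, 391), seed = 1L) {
  stopifnot(k >= 2, tau2 >= 0, p0 > 0, p0 < 1)
  pick_sizes <- function(x) {
    if (length(x) == k) return(as.integer(x))
    if (length(x) == 2L) {
      return(as.integer(round(stats::runif(k, min(x), max(x)))))
    }
    stop("arm sizes must be a length-2 range or a length-k vector",
         call. = FALSE)
  }
  withr::with_seed(seed, {
    nc <- pick_sizes(n_cases)
    nk <- pick_sizes(n_controls)
    draw <- function(i) {
      for (try in seq_len(100L)) {
        or_i <- exp(stats::rnorm(1L, theta, sqrt(tau2)))
        p1 <- or_i * p0 / (1 - p0 + or_i * p0)
        a <- stats::rbinom(1L, nc[i], p1)   # case present
        b <- stats::rbinom(1L, nk[i], p0)   # control present
        cc <- nc[i] - a; dd <- nk[i] - b
        if ((a + b) > 0 && (cc + dd) > 0) {
          return(c(case_null = cc, case_present = a,
                   control_null = dd, control_present = b))
        }
      }
      stop("could not draw a non-degenerate study in 100 attempts",
           call. = FALSE)
    }
    counts <- t(vapply(seq_len(k), draw, numeric(4L)))
  })
  studies <- as_genotype_studies(data.frame(
    study_id = sprintf("sim%02d", seq_len(k)),
    ethnicity = "simulated",
    counts, stringsAsFactors = FALSE))
  structure(list(studies = studies, theta = theta, tau2 = tau2, p0 = p0,
                 seed = seed),
            class = "meta_sim")
}

# printed Total rows the study fixtures are checked against at load
.fixture_totals <- list(
  gstm1_atdh = c(case_null = 348, case_present = 331,
                 control_null = 981, control_present = 1308),
  gstt1_atdh = c(case_null = 231, case_present = 433,
                 control_null = 879, control_present = 1653),
  gstm1_scz  = c(case_null = 833, case_present = 636,
                 control_null = 821, control_present = 784),
  gstt1_scz  = c(case_null = 292, case_present = 644,
                 control_null = 375, control_present = 596))

#' Load a packaged fixture
#'
#' Returns one of the packaged data sets: the four transcribed GSTM1/GSTT1
#' genotype study tables (hepatotoxicity and schizophrenia case-control
#' series) or the toy interaction network. Study fixtures are verified
#' against their published column totals at load time; a mismatch raises a
#' corrupted-fixture error. The `gstt1_atdh` table carries attribute
#' `known_inconsistency = TRUE`: the published table duplicates two study
#' rows and its totals disagree with the accompanying narrative, so exact
#' pooled values from it should not be asserted against the published ones.
#'
#' @param name one of `"gstm1_atdh"`, `"gstt1_atdh"`, `"gstm1_scz"`,
#'   `"gstt1_scz"`, `"toy_network"`.
#' @return a `genotype_studies` table, or a [ppi_network()] for
#'   `"toy_network"`.
#' @export
load_fixture <- function(name) {
  choices <- c(names(.fixture_totals), "toy_network")
  if (length(name) != 1L || !name %in% choices) {
    stop("unknown fixture: ", paste(name, collapse = ", "),
         " (available: ", paste(choices, collapse = ", "), ")",
         call. = FALSE)
  }
  if (name == "toy_network") {
    path <- system.file("extdata", "toy_network.tsv", package = "driverscan",
                        mustWork = TRUE)
    return(read_edge_list(path, score_threshold = 0.9, score_scale = "unit"))
  }
  path <- system.file("extdata", paste0(name, ".csv"), package = "driverscan",
                      mustWork = TRUE)
  d <- read_studies(path)
  expected <- .fixture_totals[[name]]
  got <- vapply(names(expected), function(cl) sum(d[[cl]]), numeric(1L))
  if (!all(got == expected)) {
    stop("fixture ", name, " is corrupted: column totals ",
         paste(got, collapse = "/"), " != expected ",
         paste(expected, collapse = "/"), call. = FALSE)
  }
  if (name == "gstt1_atdh") attr(d, "known_inconsistency") <- TRUE
  d
}
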