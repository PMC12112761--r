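# run code under a local RNG stream without disturbing the caller's RNG
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv()))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  force(code)
}

#' Specify a synthetic incidence-matrix generator
#'
#' A generator spec fixes the number of samples, the exact incidence of
#' every taxon (its column sum — matched exactly, not in expectation), an
#' optional list of planted pairwise associations, and a seed. Under the
#' null, each taxon's presence set is an independent uniform random subset
#' of the samples, which is exactly the placement model assumed by the
#' hypergeometric pair test.
#'
#' @param n_samples number of samples (matrix rows).
#' @param taxon_incidences named integer vector: taxon label -> incidence;
#'   every value must lie in [0, n_samples].
#' @param planted_pairs optional data frame with columns \code{taxon_a},
#'   \code{taxon_b}, \code{target_overlap}: after the null draw, each
#'   \code{taxon_b} column is re-drawn to share exactly
#'   \code{target_overlap} samples with \code{taxon_a}. A taxon may anchor
#'   several plantings (appear as \code{taxon_a}), but a re-drawn
#'   \code{taxon_b} may not take part in any other planted pair.
#' @param seed RNG seed.
#' @return object of class \code{generator_spec}.
#' @export
generator_spec <- function(n_samples, taxon_incidences, planted_pairs = NULL,
                           seed = NULL) {
  if (n_samples < 1) stop("n_samples must be >= 1")
  if (is.null(names(taxon_incidences)) || anyDuplicated(names(taxon_incidences))) {
    stop("taxon_incidences must be uniquely named")
  }
  if (any(taxon_incidences < 0 | taxon_incidences > n_samples)) {
    bad <- names(taxon_incidences)[taxon_incidences > n_samples |
                                     taxon_incidences < 0][1]
    stop("incidence out of [0, n_samples] for taxon: ", bad)
  }
  if (!is.null(planted_pairs)) {
    planted_pairs <- as.data.frame(planted_pairs, stringsAsFactors = FALSE)
    need <- c("taxon_a", "taxon_b", "target_overlap")
    if (!all(need %in% names(planted_pairs))) {
      stop("planted_pairs needs columns ", paste(need, collapse = ", "))
    }
    for (k in seq_len(nrow(planted_pairs))) {
      pa <- planted_pairs$taxon_a[k]; pb <- planted_pairs$taxon_b[k]
      if (!pa %in% names(taxon_incidences) || !pb %in% names(taxon_incidences)) {
        stop("planted pair names an unknown taxon: ", pa, " / ", pb)
      }
      check_overlap_feasible(n_samples, taxon_incidences[[pa]],
                             taxon_incidences[[pb]],
                             planted_pairs$target_overlap[k])
      others <- planted_pairs[-k, , drop = FALSE]
      if (pb %in% c(others$taxon_a, others$taxon_b)) {
        stop("planted pairs overlap on re-drawn taxon: ", pb)
      }
    }
  }
  structure(list(n_samples = as.integer(n_samples),
                 taxon_incidences = taxon_incidences,
                 planted_pairs = planted_pairs,
                 seed = seed),
            class = "generator_spec")
}

check_overlap_feasible <- function(n, n1, n2, j) {
  lo <- max(0L, n1 + n2 - n)
  hi <- min(n1, n2)
  if (j < lo || j > hi) {
    stop(sprintf("target overlap %s infeasible for incidences %d, %d in %d samples (support [%d, %d])",
                 j, n1, n2, n, lo, hi))
  }
  invisible(TRUE)
}

#' Draw an incidence matrix under the independence null
#'
#' Each taxon's presence set is a uniform random subset of samples of its
#' requested size, independently across taxa. Column sums always match the
#' spec exactly; row sums are free.
#'
#' @param spec a \code{\link{generator_spec}} without planted pairs (any
#'   planted pairs present are ignored here; see
#'   \code{\link{generate_matrix}}).
#' @param seed optional seed overriding the spec's.
#' @return an \code{\link{incidence_matrix}} of dimension
#'   n_samples x n_taxa.
#' @export
sample_null_matrix <- function(spec, seed = NULL) {
  stopifnot(inherits(spec, "generator_spec"))
  seed <- if (is.null(seed)) spec$seed else seed
  inc <- spec$taxon_incidences
  n <- spec$n_samples
  m <- matrix(0L, nrow = n, ncol = length(inc),
              dimnames = list(paste0("sample_", seq_len(n)), names(inc)))
  with_seed(seed, {
    for (t in seq_along(inc)) {
      if (inc[[t]] > 0L) m[sample.int(n, inc[[t]]), t] <- 1L
    }
  })
  incidence_matrix(m)
}

#' Re-draw one taxon to share a fixed number of samples with another
#'
#' Taxon \code{taxon_b}'s presence set is replaced by a uniform draw among
#' all placements with exactly \code{target_overlap} samples in common with
#' \code{taxon_a}; both column sums are preserved and all other columns are
#' untouched. Used to plant positive (high overlap) or negative (low
#' overlap) associations in otherwise-null matrices.
#'
#' @param x an \code{\link{incidence_matrix}}.
#' @param taxon_a,taxon_b taxon labels present in \code{x}.
#' @param target_overlap desired number of shared samples; must be feasible
#'   given both incidences and the sample count.
#' @param seed RNG seed.
#' @return the modified \code{\link{incidence_matrix}}.
#' @export
plant_association <- function(x, taxon_a, taxon_b, target_overlap, seed = NULL) {
  x <- incidence_matrix(x)
  if (!taxon_a %in% colnames(x)) stop("unknown taxon: ", taxon_a)
  if (!taxon_b %in% colnames(x)) stop("unknown taxon: ", taxon_b)
  n <- nrow(x)
  n1 <- sum(x[, taxon_a])
  n2 <- sum(x[, taxon_b])
  check_overlap_feasible(n, n1, n2, target_overlap)
  inside <- which(x[, taxon_a] == 1L)
  outside <- which(x[, taxon_a] == 0L)
  with_seed(seed, {
    pick_in <- if (target_overlap > 0)
      inside[sample.int(length(inside), target_overlap)] else integer(0)
    k_out <- n2 - target_overlap
    pick_out <- if (k_out > 0)
      outside[sample.int(length(outside), k_out)] else integer(0)
    x[, taxon_b] <- 0L
    x[c(pick_in, pick_out), taxon_b] <- 1L
  })
  x
}

#' Generate a matrix from a spec, planting any requested associations
#'
#' Draws the null matrix, then applies each planted pair in order via
#' \code{\link{plant_association}} (a single RNG stream seeded once drives
#' both stages, so identical spec + seed gives an identical matrix).
#'
#' @param spec a \code{\link{generator_spec}}.
#' @param seed optional seed overriding the spec's.
#' @return an \code{\link{incidence_matrix}}.
#' @export
generate_matrix <- function(spec, seed = NULL) {
  stopifnot(inherits(spec, "generator_spec"))
  seed <- if (is.null(seed)) spec$seed else seed
  with_seed(seed, {
    m <- sample_null_matrix(spec, seed = NULL)
    if (!is.null(spec$planted_pairs)) {
      for (k in seq_len(nrow(spec$planted_pairs))) {
        m <- plant_association(m, spec$planted_pairs$taxon_a[k],
                               spec$planted_pairs$taxon_b[k],
                               spec$planted_pairs$target_overlap[k],
                               seed = NULL)
      }
    }
    m
  })
}

#' Taxon table of the granite-gneiss biocrust study
#'
#' The 23 taxa recorded in 38 biocrust samples from a tropical
#' granite-gneiss outcrop, with phylum, family and incidence (number of
#' samples containing the taxon). Incidences follow the published
#' frequency table; the six phyla are Cyanobacteria, Chlorophyta,
#' Charophyta, Bacillariophyta, Bryophyta and Marchantiophyta.
#'
#' @return data frame with columns \code{taxon_id}, \code{phylum},
#'   \code{family}, \code{incidence}.
#' @export
study_taxa <- function() {
  data.frame(
    taxon_id = c("Cyanothece", "Gloeothece", "Microcoleus", "Nostoc",
                 "Scytonema", "Stigonema", "Chlorococcum", "Gloeocystis",
                 "Actinotaenium", "Euastrum", "Zygogonium",
                 "Pinnularia borealis", "Anomobryum conicum",
                 "Bryum arachnoideum", "Bryum argenteum", "Bryum atenense",
                 "Bryum orthodontioides", "Campylopus lamellatus",
                 "Dicranella lindigiana", "Fabronia ciliaris",
                 "Fissidens weirii", "Cylindrocolea rhizantha",
                 "Riccia weinionis"),
    phylum = c(rep("Cyanobacteria", 6), rep("Chlorophyta", 2),
               rep("Charophyta", 3), "Bacillariophyta",
               rep("Bryophyta", 9), rep("Marchantiophyta", 2)),
    family = c("Cyanothecaceae", "Microcystaceae", "Microcoleaceae",
               "Nostocaceae", "Scytonemataceae", "Stigonemataceae",
               "Chlorococcaceae", "Radiococcaceae", "Desmidiaceae",
               "Desmidiaceae", "Zygnemataceae", "Pinnulariaceae",
               "Bryaceae", "Bryaceae", "Bryaceae", "Bryaceae", "Bryaceae",
               "Dicranaceae", "Dicranaceae", "Fabroniaceae",
               "Fissidentaceae", "Cephaloziellaceae", "Ricciaceae"),
    incidence = c(5L, 3L, 11L, 11L, 34L, 6L, 7L, 4L, 4L, 1L, 6L, 4L,
                  14L, 3L, 17L, 15L, 1L, 7L, 2L, 1L, 1L, 1L, 8L),
    stringsAsFactors = FALSE)
}

#' Study-shaped synthetic incidence matrix
#'
#' Generates a 38-sample by 23-taxon matrix whose column sums equal the
#' published per-taxon incidences, with two associations planted to mirror
#' the study's strongest signals: \emph{Riccia weinionis} and \emph{Nostoc}
#' at their maximal overlap (all 8 \emph{Riccia} samples also contain
#' \emph{Nostoc}), and \emph{Riccia weinionis} and \emph{Bryum atenense}
#' disjoint. The raw study matrix is unpublished, so this fixture
#' reproduces the marginals and the direction of those associations, not
#' the remaining pairs' exact overlaps.
#'
#' @param seed RNG seed.
#' @param plant logical; set \code{FALSE} for a pure null draw with the
#'   study marginals.
#' @return list with \code{matrix} (an \code{\link{incidence_matrix}}) and
#'   \code{metadata} (the \code{\link{study_taxa}} table).
#' @examples
#' fx <- study_fixture(seed = 1)
#' dim(fx$matrix)
#' @export
study_fixture <- function(seed = NULL, plant = TRUE) {
  taxa <- study_taxa()
  inc <- stats::setNames(taxa$incidence, taxa$taxon_id)
  planted <- if (plant) {
    data.frame(taxon_a = c("Riccia weinionis", "Riccia weinionis"),
               taxon_b = c("Nostoc", "Bryum atenense"),
               target_overlap = c(8L, 0L), stringsAsFactors = FALSE)
  } else NULL
  spec <- generator_spec(38, inc, planted_pairs = planted, seed = seed)
  list(matrix = generate_matrix(spec), metadata = taxa)
}

#' Read a generator spec from a YAML or JSON config file
#'
#' The file must define \code{n_samples}, \code{taxon_incidences} (a map
#' taxon -> count), and may define \code{planted_pairs} (a list of records
#' with \code{taxon_a}, \code{taxon_b}, \code{target_overlap}) and
#' \code{seed}.
#'
#' @param path file path; format chosen by extension (\code{.json} vs
#'   \code{.yml}/\code{.yaml}).
#' @return a \code{\link{generator_spec}}.
#' @export
read_generator_spec <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("the 'yaml' package is required to read YAML specs")
    }
    yaml::read_yaml(path)
  }
  if (is.null(cfg$n_samples) || is.null(cfg$taxon_incidences)) {
    stop("spec must define n_samples and taxon_incidences")
  }
  planted <- cfg$planted_pairs
  if (!is.null(planted) && !is.data.frame(planted)) {
    planted <- do.call(rbind, lapply(planted, as.data.frame,
                                     stringsAsFactors = FALSE))
  }
  generator_spec(cfg$n_samples, unlist(cfg$taxon_incidences),
                 planted_pairs = planted, seed = cfg$seed)
}
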