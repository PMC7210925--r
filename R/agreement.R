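#' The graded biomarkers
#'
#' Column order of the ten binary biomarker flags in grading tables:
#' intraretinal fluid (IRF), subretinal fluid (SRF), epiretinal membrane
#' (ERM), drusen, reticular pseudodrusen (RPD), geographic atrophy (GA),
#' incomplete RPE and outer retinal atrophy (iRORA), pigment epithelial
#' detachment (PED), hyperreflective foci/exudates (HE), and
#' scarring/fibrosis (SCAR_FIB).
#'
#' @export
BIOMARKERS <- c("IRF", "SRF", "ERM", "Drusen", "RPD", "GA", "iRORA", "PED",
                "HE", "SCAR_FIB")

#' Cohen's kappa for two binary raters
#'
#' Chance-corrected agreement `kappa = (p_o - p_e) / (1 - p_e)` from the
#' 2 x 2 contingency of the two label vectors. If both raters are constant
#' and identical (`p_e = 1`), kappa is defined as 1 by convention; constant
#' but unequal raters fall through to the formula (`p_e < 1`).
#'
#' @param labels_a,labels_b Equal-length logical (or 0/1) vectors.
#' @return A tibble with `kappa`, `observed_agreement`, `chance_agreement`,
#'   `n`.
#' @export
cohens_kappa <- function(labels_a, labels_b) {
  if (length(labels_a) != length(labels_b)) {
    stop_invalid("label vectors differ in length")
  }
  if (!length(labels_a)) stop_invalid("empty label vectors")
  a <- as.logical(labels_a); b <- as.logical(labels_b)
  n <- length(a)
  p_o <- mean(a == b)
  p_e <- mean(a) * mean(b) + mean(!a) * mean(!b)
  kappa <- if (p_e >= 1) 1 else (p_o - p_e) / (1 - p_e)
  tibble::tibble(kappa = kappa, observed_agreement = p_o,
                 chance_agreement = p_e, n = n)
}

# Exact null distribution of the signed-rank sum over doubled midranks
# (doubling makes tied half-ranks integral): probability vector over
# achievable doubled sums 0..sum(2r).
signed_rank_null <- function(ranks2) {
  dist <- numeric(sum(ranks2) + 1L)
  dist[1L] <- 1
  for (r in ranks2) {
    shifted <- c(numeric(r), dist[seq_len(length(dist) - r)])
    dist <- (dist + shifted) / 2
  }
  dist
}

#' Wilcoxon signed-rank test for paired quality scores
#'
#' Standard signed-rank conventions, pinned for reproducibility: zero
#' differences are dropped, ties receive midranks, the statistic `V` is the
#' rank sum of positive differences, and the two-sided p-value is exact
#' (full convolution of the signed-rank null, valid under ties) for up to
#' 25 nonzero differences, with a normal approximation including the tie
#' correction beyond that.
#'
#' @param pre,post Equal-length numeric vectors (e.g. 1-10 quality scores),
#'   paired by image.
#' @return A tibble with `statistic` (V), `p_value`, `n_nonzero`, `method`.
#' @export
wilcoxon_quality <- function(pre, post) {
  if (length(pre) != length(post)) stop_invalid("length mismatch")
  d <- post - pre
  d <- d[d != 0]
  if (!length(d)) stop_invalid("all differences are zero (degenerate)")
  n <- length(d)
  r <- rank(abs(d))
  v <- sum(r[d > 0])
  if (n <= 25L) {
    ranks2 <- as.integer(round(2 * r))
    dist <- signed_rank_null(ranks2)
    v2 <- as.integer(round(2 * v))
    p_lo <- sum(dist[seq_len(v2 + 1L)])
    p_hi <- sum(dist[(v2 + 1L):length(dist)])
    p <- min(1, 2 * min(p_lo, p_hi))
    method <- "exact"
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(r)
    sig2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    z <- (v - mu) / sqrt(sig2)
    p <- 2 * pnorm(-abs(z))
    method <- "normal approximation"
  }
  tibble::tibble(statistic = v, p_value = p, n_nonzero = n, method = method)
}

validate_grading_records <- function(records) {
  required <- c("image_id", "grader_id", "condition", BIOMARKERS, "quality")
  missing_cols <- setdiff(required, names(records))
  if (length(missing_cols)) {
    stop_invalid("grading table lacks columns: %s",
                 paste(missing_cols, collapse = ", "))
  }
  graders <- sort(unique(records$grader_id))
  if (length(graders) != 2) {
    stop_invalid("expected exactly 2 distinct graders, found %d",
                 length(graders))
  }
  if (!all(records$condition %in% c("original", "enhanced"))) {
    stop_invalid("condition must be 'original' or 'enhanced'")
  }
  if (!all(records$quality %in% 1:10)) {
    stop_invalid("quality scores must be integers in 1..10")
  }
  counts <- dplyr::count(records, .data$image_id, .data$condition)
  bad <- dplyr::filter(counts, .data$n != 2)
  if (nrow(bad)) {
    stop_invalid("images lacking both graders' records: %s",
                 paste(utils::head(paste(bad$image_id, bad$condition, sep = "/"),
                                   5), collapse = ", "))
  }
  graders
}

#' Intergrader agreement report
#'
#' For each biomarker and each condition (original / enhanced images),
#' computes Cohen's kappa between the two graders across images; for each
#' grader, compares subjective quality on original vs enhanced images with
#' the Wilcoxon signed-rank test. No inferential comparison between kappa
#' values is performed.
#'
#' @param records Tidy grading table: one row per (image, grader,
#'   condition) with the ten biomarker flag columns and a `quality` score
#'   (see [BIOMARKERS] and [read_grading_csv()]).
#' @return An `oct_agreement` list: `kappa` tibble (biomarker x condition),
#'   `quality_tests` tibble (per grader), `quality_histogram` tibble.
#' @export
agreement_report <- function(records) {
  records <- tibble::as_tibble(records)
  graders <- validate_grading_records(records)
  wide <- function(cond, marker) {
    sub <- dplyr::filter(records, .data$condition == cond)
    sub <- dplyr::arrange(sub, .data$image_id)
    list(a = sub[[marker]][sub$grader_id == graders[1]],
         b = sub[[marker]][sub$grader_id == graders[2]])
  }
  kappa <- purrr::map_dfr(BIOMARKERS, function(marker) {
    purrr::map_dfr(c("original", "enhanced"), function(cond) {
      ab <- wide(cond, marker)
      dplyr::mutate(cohens_kappa(ab$a, ab$b),
                    biomarker = marker, condition = cond, .before = 1)
    })
  })
  quality_tests <- purrr::map_dfr(graders, function(g) {
    sub <- dplyr::arrange(dplyr::filter(records, .data$grader_id == g),
                          .data$image_id)
    pre <- sub$quality[sub$condition == "original"]
    post <- sub$quality[sub$condition == "enhanced"]
    dplyr::mutate(wilcoxon_quality(pre, post), grader_id = g, .before = 1)
  })
  quality_histogram <- dplyr::count(records, .data$grader_id,
                                    .data$condition, .data$quality)
  structure(list(kappa = kappa, quality_tests = quality_tests,
                 quality_histogram = quality_histogram),
            class = "oct_agreement")
}

#' @exportS3Method generics::tidy
tidy.oct_agreement <- function(x, ...) x$kappa

#' @exportS3Method generics::glance
glance.oct_agreement <- function(x, ...) x$quality_tests

#' @export
print.oct_agreement <- function(x, ...) {
  cat("Intergrader agreement (Cohen's kappa)\n")
  wide <- tidyr::pivot_wider(x$kappa[, c("biomarker", "condition", "kappa")],
                             names_from = "condition", values_from = "kappa")
  print.data.frame(as.data.frame(wide), digits = 3, row.names = FALSE)
  cat("\nSubjective quality, original vs enhanced (Wilcoxon signed-rank)\n")
  print.data.frame(as.data.frame(x$quality_tests), digits = 3,
                   row.names = FALSE)
  invisible(x)
}

#' Simulate a grading study with a planted agreement model
#'
#' Generates records for two graders over `n_images` under a flip model:
#' each image has a latent truth per biomarker (prevalence `prevalence`),
#' and each grader independently flips each flag with probability `q`
#' (`q_original` / `q_enhanced` per condition). Under this model the
#' analytic kappa is available from [flip_model_kappa()], which makes the
#' generator a calibration tool for the agreement machinery. Quality scores
#' are drawn around a condition-dependent mean to emulate the subjective
#' improvement after enhancement.
#'
#' @param n_images Number of images.
#' @param q_original,q_enhanced Per-grader flip probabilities by condition.
#' @param prevalence Latent biomarker prevalence.
#' @param quality_shift Mean subjective-quality gain of enhanced images (in
#'   score points).
#' @param seed Integer seed.
#' @return Tidy grading tibble suitable for [agreement_report()].
#' @export
simulate_grading_records <- function(n_images, q_original = 0.1,
                                     q_enhanced = q_original,
                                     prevalence = 0.3, quality_shift = 2,
                                     seed = 1L) {
  with_local_seed(seed, {
    truth <- matrix(runif(n_images * length(BIOMARKERS)) < prevalence,
                    n_images, length(BIOMARKERS),
                    dimnames = list(NULL, BIOMARKERS))
    one_condition <- function(cond, q) {
      purrr::map_dfr(c("grader1", "grader2"), function(g) {
        flips <- matrix(runif(length(truth)) < q, nrow(truth), ncol(truth))
        obs <- xor(truth, flips)
        base_q <- if (cond == "original") 5 else 5 + quality_shift
        qual <- pmin(pmax(round(rnorm(n_images, base_q, 1.5)), 1), 10)
        dplyr::bind_cols(
          tibble::tibble(image_id = sprintf("img%05d", seq_len(n_images)),
                         grader_id = g, condition = cond),
          tibble::as_tibble(obs),
          tibble::tibble(quality = as.integer(qual))
        )
      })
    }
    dplyr::bind_rows(one_condition("original", q_original),
                     one_condition("enhanced", q_enhanced))
  })
}

#' Analytic kappa of the symmetric flip model
#'
#' For two graders who observe a latent flag of prevalence `prevalence`
#' and each flip it independently with probability `q`: observed agreement
#' is `(1-q)^2 + q^2` (independent of prevalence) and both marginals equal
#' `prevalence + q (1 - 2 prevalence)`.
#'
#' @param q Flip probability.
#' @param prevalence Latent flag prevalence.
#' @return The population Cohen's kappa.
#' @export
flip_model_kappa <- function(q, prevalence = 0.3) {
  p_o <- (1 - q)^2 + q^2
  m <- prevalence + q * (1 - 2 * prevalence)
  p_e <- m^2 + (1 - m)^2
  if (p_e >= 1) return(1)
  (p_o - p_e) / (1 - p_e)
}
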