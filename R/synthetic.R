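# Synthetic inputs with the statistical structure the pipeline assumes:
# planted directional clusters on the unit sphere (von Mises-Fisher
# mixtures) and template-based question corpora with known category
# labels and varying section paths.

# One draw of the cosine w = <x, mu> under vMF(kappa) in d dimensions,
# by the Ulrich (1984) / Wood (1994) rejection sampler.
#' @keywords internal
rvmf_w <- function(n, kappa, d) {
  if (kappa == 0) {
    # uniform sphere: w has density prop. to (1 - w^2)^((d-3)/2)
    return(2 * stats::rbeta(n, (d - 1) / 2, (d - 1) / 2) - 1)
  }
  b <- (-2 * kappa + sqrt(4 * kappa^2 + (d - 1)^2)) / (d - 1)
  x0 <- (1 - b) / (1 + b)
  c0 <- kappa * x0 + (d - 1) * log(1 - x0^2)
  out <- numeric(n)
  got <- 0L
  while (got < n) {
    m <- n - got
    Z <- stats::rbeta(m, (d - 1) / 2, (d - 1) / 2)
    W <- (1 - (1 + b) * Z) / (1 - (1 - b) * Z)
    U <- stats::runif(m)
    ok <- kappa * W + (d - 1) * log(1 - x0 * W) - c0 >= log(U)
    keep <- W[ok]
    if (length(keep) > 0) {
      out[(got + 1):(got + length(keep))] <- keep
      got <- got + length(keep)
    }
  }
  out
}

#' Draw from a von Mises-Fisher distribution
#'
#' Samples unit vectors concentrated around `mu` with concentration
#' `kappa` (`kappa = 0` gives the uniform distribution on the sphere).
#' Uses the Ulrich/Wood rejection sampler for the cosine to the mean and a
#' Householder reflection to rotate onto `mu`.  The caller controls the
#' RNG state.
#'
#' @param n number of draws.
#' @param mu mean direction (any nonzero vector; normalized internally).
#' @param kappa concentration, `>= 0`.
#' @return an `n x length(mu)` matrix of unit rows.
#' @export
rvmf <- function(n, mu, kappa) {
  d <- length(mu)
  stopifnot(d >= 2, kappa >= 0)
  mu <- mu / sqrt(sum(mu^2))
  w <- rvmf_w(n, kappa, d)
  # tangential part: uniform on the (d-2)-sphere
  V <- matrix(stats::rnorm(n * (d - 1)), n, d - 1)
  V <- V / sqrt(rowSums(V^2))
  X <- cbind(w, sqrt(pmax(1 - w^2, 0)) * V)   # samples around e1
  # Householder reflection mapping e1 to mu
  e1 <- c(1, rep(0, d - 1))
  u <- e1 - mu
  un <- sqrt(sum(u^2))
  if (un > 1e-12) {
    u <- u / un
    X <- X - 2 * (X %*% u) %*% t(u)   # reflect: X - 2 (X u) u'
  }
  X
}

#' Sample a planted mixture of von Mises-Fisher components
#'
#' Component mean directions are drawn uniformly on the sphere subject to
#' a maximum pairwise cosine (minimum angular separation), then `n` points
#' are drawn from the mixture with the given component weights and common
#' concentration `kappa`.  Everything is deterministic given `seed`.
#'
#' @param n number of points.
#' @param d ambient dimension, `>= 2`.
#' @param k number of components.
#' @param kappa common concentration (`0` = uniform sphere, no structure).
#' @param weights mixture weights (default uniform); must sum to 1.
#' @param max_pairwise_cos separation constraint on the component means:
#'   every pair of means must have cosine `<=` this value.
#' @param seed integer seed.
#' @param max_tries resampling attempts for the separation constraint.
#' @return object of class `planted_dataset`: `X` (n x d unit rows),
#'   `labels` (1-based component of each point), `means` (k x d unit
#'   rows), `kappa`, `weights`, `seed`, `min_separation` (smallest
#'   pairwise angle between means, radians).
#' @export
sample_vmf_mixture <- function(n, d, k, kappa, weights = NULL,
                               max_pairwise_cos = 0.7, seed = 1L,
                               max_tries = 200) {
  stopifnot(d >= 2, kappa >= 0, k >= 1, n >= 1)
  if (is.null(weights)) weights <- rep(1 / k, k)
  if (length(weights) != k || abs(sum(weights) - 1) > 1e-8) {
    stop("weights must have length k and sum to 1", call. = FALSE)
  }
  with_seed(seed, {
    means <- NULL
    for (try in seq_len(max_tries)) {
      M <- matrix(stats::rnorm(k * d), k, d)
      M <- M / sqrt(rowSums(M^2))
      if (k == 1 || max(tcrossprod(M)[upper.tri(diag(k))]) <= max_pairwise_cos) {
        means <- M
        break
      }
    }
    if (is.null(means)) {
      stop("could not place ", k, " means with pairwise cosine <= ",
           max_pairwise_cos, " in ", max_tries, " tries; relax the ",
           "separation constraint or reduce k", call. = FALSE)
    }
    labels <- sample.int(k, n, replace = TRUE, prob = weights)
    X <- matrix(0, n, d)
    for (j in seq_len(k)) {
      idx <- which(labels == j)
      if (length(idx) > 0) X[idx, ] <- rvmf(length(idx), means[j, ], kappa)
    }
    # smallest angle between means = acos of the largest pairwise cosine
    min_sep <- if (k > 1) {
      acos(min(max(tcrossprod(means)[upper.tri(diag(k))], -1), 1))
    } else NA_real_
    structure(list(X = X, labels = labels, means = means, kappa = kappa,
                   weights = weights, seed = as.integer(seed),
                   min_separation = min_sep),
              class = "planted_dataset")
  })
}

#' @export
print.planted_dataset <- function(x, ...) {
  cat(sprintf("<planted_dataset> n = %d, d = %d, k = %d, kappa = %g\n",
              nrow(x$X), ncol(x$X), nrow(x$means), x$kappa))
  invisible(x)
}

# Paraphrase template bank keyed to the top-level SDOH categories of the
# bundled taxonomy.  Each category has several wordings of the same
# underlying questions, plus alternative section titles, emulating how the
# same item shows up across site-specific intake forms.
#' @keywords internal
question_template_bank <- function() {
  list(
    Health = list(
      sections = c("health/Medical History/", "Medical Data/",
                   "clinical/Health Status/"),
      templates = c("Do you have any current medical conditions",
                    "Please list any ongoing health problems",
                    "How would you rate your overall health",
                    "Have you been diagnosed with any chronic illness",
                    "Are you currently taking any prescribed medication")),
    Family = list(
      sections = c("family/Relationships/", "Family Data/",
                   "social/Family History/"),
      templates = c("Who do you currently live with",
                    "How many children do you have",
                    "Do you have a supportive relationship with your family",
                    "Describe your relationship with your children",
                    "Is there a family history of illness")),
    Education = list(
      sections = c("economic/Education/", "Educational Data/",
                   "social/Education History/"),
      templates = c("What Is The Highest Grade You Have Completed",
                    "Highest grade attained",
                    "What degrees or diplomas do you hold",
                    "Did you complete high school",
                    "Are you currently enrolled in any educational program")),
    Employment = list(
      sections = c("economic/Employment/", "Employment Data/",
                   "work/Occupational History/"),
      templates = c("What is your current employment status",
                    "Are you currently employed",
                    "What is your main source of income",
                    "How long have you been at your current job",
                    "Do you receive any employment benefits")),
    Housing = list(
      sections = c("housing/Living Situation/", "Housing Data/",
                   "social/Residence/"),
      templates = c("What is your current living situation",
                    "Do you have stable housing",
                    "How many people live in your household",
                    "Have you ever experienced homelessness",
                    "Do you have reliable transportation")),
    Legal = list(
      sections = c("legal/Legal History/", "Legal Data/",
                   "justice/Criminal Record/"),
      templates = c("Have you ever been arrested",
                    "Are you currently on parole or probation",
                    "Have you ever been incarcerated",
                    "Do you have any pending court cases",
                    "Is your treatment mandated by a court")),
    Demographics = list(
      sections = c("demographics/Basic Information/", "Demographic Data/",
                   "intake/Personal Details/"),
      templates = c("What is your date of birth",
                    "What is your race or ethnicity",
                    "What is your primary language",
                    "What is your zip code",
                    "What is your sex")),
    Spirituality = list(
      sections = c("spirituality/Beliefs/", "Spiritual Data/",
                   "personal/Faith/"),
      templates = c("Do you consider yourself spiritual or religious",
                    "Is religion an important part of your life",
                    "Do you attend religious services",
                    "Does faith play a role in your recovery"))
  )
}

#' Generate a synthetic question corpus with known categories
#'
#' Fills paraphrase templates from a built-in bank (keyed to the top-level
#' categories of the bundled SDOH taxonomy) and assigns randomized section
#' paths, so the same question text appears under different field paths —
#' the path variation that inflates path+text distinct counts over
#' text-only counts on real intake forms.  A fraction of records are exact
#' duplicates of earlier ones under a different path so deduplication is
#' exercised.
#'
#' @param categories category names; must be keys of the template bank
#'   (see [synthetic_categories()]).
#' @param n_per_category records generated per category.
#' @param duplicate_rate fraction of extra records that re-emit an earlier
#'   question under a different section path.
#' @param seed integer seed.
#' @return object of class `synthetic_corpus`: `records` (a
#'   `question_records` data frame), `true_category` (named character,
#'   record_id -> category), `templates_used` (named character,
#'   record_id -> template text).
#' @export
generate_question_corpus <- function(categories, n_per_category = 10,
                                     duplicate_rate = 0.2, seed = 1L) {
  bank <- question_template_bank()
  unknown <- setdiff(categories, names(bank))
  if (length(unknown) > 0) {
    stop("unknown categories: ", paste(unknown, collapse = ", "),
         "; available: ", paste(names(bank), collapse = ", "),
         call. = FALSE)
  }
  # lead-in phrasings applied on top of the base templates, so the number
  # of distinct wordings per category exceeds the template count (real
  # forms vary framing as well as core wording)
  leadins <- c("", "", "", "Please tell us: ", "For our records, ",
               "Intake question: ")
  with_seed(seed, {
    form <- path <- name <- cat_of <- tmpl <- character(0)
    for (cat in categories) {
      spec <- bank[[cat]]
      for (i in seq_len(n_per_category)) {
        t <- paste0(sample(leadins, 1), sample(spec$templates, 1))
        s <- sample(spec$sections, 1)
        form <- c(form, sprintf("F%02d", sample.int(49, 1)))
        path <- c(path, s)
        name <- c(name, t)
        cat_of <- c(cat_of, cat)
        tmpl <- c(tmpl, t)
      }
    }
    # exact duplicates under a different path
    n_dup <- round(duplicate_rate * length(name))
    if (n_dup > 0) {
      src <- sample.int(length(name), n_dup, replace = TRUE)
      for (s_i in src) {
        cat <- cat_of[s_i]
        secs <- setdiff(question_template_bank()[[cat]]$sections, path[s_i])
        new_path <- if (length(secs) > 0) sample(secs, 1) else path[s_i]
        form <- c(form, sprintf("F%02d", sample.int(49, 1)))
        path <- c(path, new_path)
        name <- c(name, name[s_i])
        cat_of <- c(cat_of, cat)
        tmpl <- c(tmpl, tmpl[s_i])
      }
    }
    records <- question_records(form_id = form, field_path = path,
                                field_name = name)
    true_category <- stats::setNames(cat_of, records$record_id)
    templates_used <- stats::setNames(tmpl, records$record_id)
    structure(list(records = records, true_category = true_category,
                   templates_used = templates_used),
              class = "synthetic_corpus")
  })
}

#' Category names available to the corpus generator
#' @return character vector of template-bank keys.
#' @export
synthetic_categories <- function() {
  names(question_template_bank())
}

#' Reference name list for a synthetic corpus
#'
#' One reference name per planted category (a short descriptive protocol
#' name built from the category's own wording), optionally padded with
#' distractor names that match no planted category — giving an end-to-end
#' mapping test with known ground truth.
#'
#' @param corpus a `synthetic_corpus`.
#' @param n_distractors number of held-out distractor names appended.
#' @return character vector of reference names; the first
#'   `length(unique categories)` entries are the true references, in the
#'   order the categories first appear.
#' @export
make_reference_taxonomy <- function(corpus, n_distractors = 0) {
  cats <- unique(corpus$true_category)
  true_refs <- paste(cats, "assessment protocol and questionnaire measures")
  distractors <- c(
    "Volcanic eruption frequency index",
    "Deep sea sonar calibration record",
    "Satellite orbital decay parameters",
    "Quantum annealing benchmark suite",
    "Glacier mass balance inventory"
  )
  if (n_distractors > length(distractors)) {
    stop("at most ", length(distractors), " distractors available",
         call. = FALSE)
  }
  c(true_refs, distractors[seq_len(n_distractors)])
}
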