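#' Build a synthetic cause model
#'
#' A cause model bundles everything needed to simulate realistic death
#' certificates and to code them deterministically: an acyclic weighted
#' causal transition graph over the vocabulary (underlying causes at the
#' roots, immediate causes downstream), a skewed prior over root causes, a
#' small rule system in the spirit of the WHO selection rules (general
#' principle, fallback to the first-mentioned sequence, Part-II promotion of
#' the AIDS/Kaposi kind, neonatal overrides, a year-dependent rule change)
#' and a reject predicate flagging certificates too complex for automatic
#' coding.
#'
#' The rule system is an intentional simplification of the WHO instruction
#' volume: it retains the properties a statistical coder has to learn
#' (lowest-line preference, Part-II promotion, age and year conditioning,
#' rejects) while staying fully deterministic and verifiable.
#'
#' @param vocab A `ucd_vocabulary`.
#' @param params Named list overriding generator defaults:
#'   `depth_probs` (chain length 1..4 distribution, default
#'   `c(.25,.35,.25,.15)` so Part I line 4 is used < 20% of the time),
#'   `comorbidity_prob` (0.3), `promo_prob` (0.08), `noise_prob` (0.1),
#'   `n_promotion_pairs` (3), `n_neonatal` (5), `n_rule_change` (2),
#'   `rule_change_year` (2012), `rule_change_weight` (0.04, UCD-prior share
#'   of the first remapped cause), `reject_min_codes` (4), `root_frac` (0.4),
#'   `mean_children` (2), `child_window` (30), plus the demographic sampler
#'   settings `base_year` (2000), `n_years` (16), `p_neonate` (0.02),
#'   `p_infant` (0.02).
#' @param seed Integer seed; identical `(vocab, params, seed)` yield an
#'   identical model.
#' @return Object of class `ucd_cause_model`.
#' @export
make_cause_model <- function(vocab, params = list(), seed = 1L) {
  stopifnot(inherits(vocab, "ucd_vocabulary"))
  p <- utils::modifyList(list(
    depth_probs = c(0.25, 0.35, 0.25, 0.15),
    comorbidity_prob = 0.3,
    promo_prob = 0.08,
    noise_prob = 0.1,
    n_promotion_pairs = 3L,
    n_neonatal = 5L,
    n_rule_change = 2L,
    rule_change_year = 2012L,
    rule_change_weight = 0.04,
    reject_min_codes = 4L,
    root_frac = 0.4,
    mean_children = 2,
    child_window = 30L,
    base_year = 2000L,
    n_years = 16L,
    p_neonate = 0.02,
    p_infant = 0.02,
    comorbidity_pool_size = 15L
  ), params)
  stopifnot(
    length(p$depth_probs) == 4, all(p$depth_probs >= 0),
    abs(sum(p$depth_probs) - 1) < 1e-8,
    p$comorbidity_prob >= 0, p$comorbidity_prob <= 1,
    p$promo_prob >= 0, p$promo_prob <= 1,
    p$noise_prob >= 0, p$noise_prob <= 1,
    p$root_frac > 0, p$root_frac <= 1,
    p$reject_min_codes >= 2
  )
  V <- vocab$V
  if (V < 20) stop("cause model needs a vocabulary of at least 20 codes")

  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))

  # topological order: position 1 is root-most; edges only run forward,
  # so the transition graph is acyclic by construction
  topo <- sample(vocab$codes)
  n_roots <- ceiling(p$root_frac * V)
  roots <- topo[seq_len(n_roots)]

  children <- stats::setNames(vector("list", V), topo)
  weights <- stats::setNames(vector("list", V), topo)
  for (i in seq_len(V - 1)) {
    hi <- min(i + p$child_window, V)
    avail <- topo[(i + 1):hi]
    k <- min(length(avail), stats::rpois(1, p$mean_children))
    if (k > 0) {
      kids <- sample(avail, k)
      children[[topo[i]]] <- kids
      weights[[topo[i]]] <- stats::setNames(stats::rexp(k) + 0.1, kids)
    }
  }

  # skewed root prior (a few prevalent causes, a long tail)
  w <- stats::rexp(n_roots)^1.5
  ucd_prior <- stats::setNames(w / sum(w), roots)

  fertile_roots <- roots[vapply(roots, function(r) length(children[[r]]) > 0,
                                logical(1))]
  if (length(fertile_roots) < p$n_promotion_pairs + p$n_neonatal + p$n_rule_change) {
    stop("vocabulary too small for the requested number of special rules")
  }

  # Part-II promotion pairs (AIDS/Kaposi analog): if the trigger appears in
  # Part II while the pattern appears in Part I, the UCD becomes the trigger
  patterns <- sample(fertile_roots, p$n_promotion_pairs)
  nonroot <- setdiff(vocab$codes, roots)
  triggers <- sample(nonroot, p$n_promotion_pairs)
  promotion_pairs <- data.frame(trigger = triggers, pattern = patterns,
                                ucd = triggers, stringsAsFactors = FALSE)

  special <- c(patterns, triggers)
  neo_src <- sample(setdiff(fertile_roots, special), p$n_neonatal)
  neo_tgt <- sample(setdiff(nonroot, c(special, neo_src)), p$n_neonatal)
  neonatal_map <- stats::setNames(neo_tgt, neo_src)

  rc_src <- sample(setdiff(fertile_roots, c(special, neo_src)), p$n_rule_change)
  rc_tgt <- sample(setdiff(nonroot, c(special, neo_src, neo_tgt, rc_src)),
                   p$n_rule_change)
  rule_change <- list(year = as.integer(p$rule_change_year),
                      map = stats::setNames(rc_tgt, rc_src))

  # the first rule-changed cause is made prevalent (share rule_change_weight
  # of the UCD prior): a year-dependent recode of a vanishingly rare cause
  # would leave no visible discontinuity to harmonize away
  ucd_prior <- ucd_prior * (1 - p$rule_change_weight) /
    sum(ucd_prior[setdiff(roots, rc_src[1])])
  ucd_prior[rc_src[1]] <- p$rule_change_weight

  pool <- unique(c(sample(setdiff(vocab$codes, c(neo_src, rc_src)),
                          p$comorbidity_pool_size), triggers))

  structure(
    list(
      vocab = vocab, params = p, seed = as.integer(seed),
      topo = topo, children = children, weights = weights,
      roots = roots, ucd_prior = ucd_prior,
      promotion_pairs = promotion_pairs,
      neonatal_map = neonatal_map, rule_change = rule_change,
      comorbidity_pool = pool,
      cache = new.env(parent = emptyenv())
    ),
    class = "ucd_cause_model"
  )
}

#' @export
print.ucd_cause_model <- function(x, ...) {
  cat(sprintf(
    "<ucd_cause_model> V=%d, %d roots, %d promotion pairs, %d neonatal rules, rule change at %d\n",
    x$vocab$V, length(x$roots), nrow(x$promotion_pairs),
    length(x$neonatal_map), x$rule_change$year))
  invisible(x)
}

# memoized descendant sets (transitive closure, DAG)
descendants <- function(model, code) {
  cached <- model$cache[[code]]
  if (!is.null(cached)) return(cached)
  seen <- character(0)
  stack <- model$children[[code]]
  while (length(stack)) {
    cur <- stack[[1]]; stack <- stack[-1]
    if (cur %in% seen) next
    seen <- c(seen, cur)
    kids <- model$children[[cur]]
    if (length(kids)) stack <- c(stack, setdiff(kids, seen))
  }
  assign(code, seen, envir = model$cache)
  seen
}

reaches <- function(model, a, b) {
  a == b || b %in% descendants(model, a)
}

# shortest path length a -> b over the transition graph (Inf if unreachable)
chain_distance <- function(model, a, b) {
  if (a == b) return(0L)
  frontier <- model$children[[a]]
  d <- 1L
  seen <- character(0)
  while (length(frontier)) {
    if (b %in% frontier) return(d)
    seen <- c(seen, frontier)
    frontier <- setdiff(unique(unlist(model$children[frontier])), seen)
    d <- d + 1L
  }
  Inf
}

sample_demographics <- function(model) {
  p <- model$params
  u <- stats::runif(1)
  if (u < p$p_neonate) {
    age_value <- sample(0:27, 1); age_unit <- "days"
  } else if (u < p$p_neonate + p$p_infant) {
    age_value <- sample(28:364, 1); age_unit <- "days"
  } else {
    ages <- 1:99
    age_value <- sample(ages, 1, prob = stats::dnorm(ages, 70, 18) + 0.002)
    age_unit <- "years"
  }
  list(
    year = sample(seq(p$base_year, length.out = p$n_years), 1),
    sex = sample(0:1, 1),
    age_value = age_value, age_unit = age_unit
  )
}

#' Sample one synthetic (unlabeled) certificate
#'
#' A root cause is drawn from the UCD prior (or, in a promotion scenario,
#' set to a registered Part-I pattern with its trigger placed in Part II), a
#' forward causal chain of depth 1-4 is walked through the transition graph,
#' and the chain is written in inverse causal order: the immediate cause on
#' Part I line 1, the root on the last used Part I line. With probability
#' `comorbidity_prob` a Part II comorbidity line is added, and with
#' probability `noise_prob` a spurious code is inserted into a Part I line.
#'
#' Randomness is taken from the current R RNG state; seed with `set.seed()`
#' (or use [generate_dataset()] / [generate_corpus()]).
#'
#' @param model A `ucd_cause_model`.
#' @param demo Optional list overriding sampled demographics (fields `year`,
#'   `sex`, `age_value`, `age_unit`).
#' @param id Certificate identifier.
#' @return An unlabeled `ucd_certificate`.
#' @export
sample_certificate <- function(model, demo = NULL, id = "synthetic") {
  stopifnot(inherits(model, "ucd_cause_model"))
  p <- model$params

  promo <- stats::runif(1) < p$promo_prob && nrow(model$promotion_pairs) > 0
  if (promo) {
    pair <- model$promotion_pairs[sample.int(nrow(model$promotion_pairs), 1), ]
    root <- pair$pattern
  } else {
    root <- sample(names(model$ucd_prior), 1, prob = model$ucd_prior)
  }

  depth <- sample.int(4L, 1, prob = p$depth_probs)
  chain <- root
  while (length(chain) < depth) {
    kids <- model$children[[chain[length(chain)]]]
    if (!length(kids)) break
    w <- model$weights[[chain[length(chain)]]]
    nxt <- if (length(kids) == 1) kids else sample(kids, 1, prob = w[kids])
    chain <- c(chain, nxt)
  }
  # inverse causal order: immediate cause first, root on the last used line
  part1 <- as.list(rev(chain))

  if (stats::runif(1) < p$noise_prob) {
    spurious <- sample(model$vocab$codes, 1)
    li <- sample.int(length(part1), 1)
    line <- part1[[li]]
    pos <- sample.int(length(line) + 1L, 1)
    part1[[li]] <- append(line, spurious, after = pos - 1L)
  }

  part2 <- list()
  if (promo) {
    part2 <- list(pair$trigger)
    if (stats::runif(1) < 0.3) {
      part2 <- c(part2, list(sample(model$comorbidity_pool, 1)))
    }
  } else if (stats::runif(1) < p$comorbidity_prob) {
    n1 <- sample.int(2L, 1)
    part2 <- list(sample(model$comorbidity_pool, n1))
    if (stats::runif(1) < 0.25) {
      part2 <- c(part2, list(sample(model$comorbidity_pool, 1)))
    }
  }

  d <- sample_demographics(model)
  if (!is.null(demo)) d <- utils::modifyList(d, demo)
  new_certificate(id = id, part1 = part1, part2 = part2, sex = d$sex,
                  age_value = d$age_value, age_unit = d$age_unit,
                  year = d$year)
}

# rule application without the reject step; returns selected code + trace
oracle_select <- function(cert, model) {
  vocab <- model$vocab
  all_codes <- c(unlist(cert$part1), unlist(cert$part2))
  outside <- setdiff(all_codes, vocab$codes)
  if (length(outside)) {
    stop(sprintf("certificate code(s) outside the model vocabulary: %s",
                 paste(outside, collapse = ", ")))
  }
  p1 <- cert$part1[lengths(cert$part1) > 0]
  used <- which(lengths(cert$part1) > 0)
  trace <- character(0)

  if (length(p1) == 0) {
    # degenerate: causes only in Part II; fall back to the first Part II code
    selected <- unlist(cert$part2)[1]
    trace <- "fallback"
  } else {
    lowest <- cert$part1[[used[length(used)]]]
    above <- unlist(cert$part1[used[-length(used)]])
    if (length(lowest) == 1 &&
        all(vapply(above, function(x) reaches(model, lowest, x), logical(1)))) {
      # general principle: the single condition on the lowest used line
      # explains (directly or transitively) everything reported above it
      selected <- lowest
      trace <- "general_principle"
    } else {
      # fallback: origin of the first-mentioned causal sequence -- among the
      # Part I codes that can give rise to the first code of the first line,
      # pick the most remote one (ties: lowest line, then leftmost, then
      # vocabulary order)
      e <- cert$part1[[used[1]]][1]
      cand <- unique(unlist(cert$part1))
      cand <- cand[vapply(cand, function(a) reaches(model, a, e), logical(1))]
      if (length(cand) == 0) cand <- e
      dist <- vapply(cand, function(a) chain_distance(model, a, e), numeric(1))
      line_of <- vapply(cand, function(a) {
        max(which(vapply(cert$part1, function(l) a %in% l, logical(1))))
      }, numeric(1))
      pos_of <- vapply(seq_along(cand), function(i) {
        match(cand[i], cert$part1[[line_of[i]]])
      }, numeric(1))
      ord <- order(-dist, -line_of, pos_of, index_of(vocab, cand))
      selected <- cand[ord[1]]
      trace <- "fallback"
    }
  }

  p2_codes <- unlist(cert$part2)
  p1_codes <- unlist(cert$part1)
  for (i in seq_len(nrow(model$promotion_pairs))) {
    pair <- model$promotion_pairs[i, ]
    if (pair$trigger %in% p2_codes && pair$pattern %in% p1_codes) {
      selected <- pair$ucd
      trace <- c(trace, "promotion")
      break
    }
  }

  if (bin_age(cert$age_value, cert$age_unit) == 0L &&
      selected %in% names(model$neonatal_map)) {
    selected <- unname(model$neonatal_map[selected])
    trace <- c(trace, "neonatal")
  }

  if (cert$year >= model$rule_change$year &&
      selected %in% names(model$rule_change$map)) {
    selected <- unname(model$rule_change$map[selected])
    trace <- c(trace, "year_rule")
  }

  list(selected = selected, trace = trace)
}

oracle_reject <- function(cert, model, trace) {
  n_codes <- sum(lengths(cert$part1)) + sum(lengths(cert$part2))
  trace[1] == "fallback" && n_codes >= model$params$reject_min_codes
}

#' Deterministically code a certificate with the rule-based oracle
#'
#' Applies, in order: (1) the general principle -- select the single
#' condition on the lowest used Part I line if the transition graph links it
#' (directly or transitively) to every condition reported above it; (2) a
#' fallback to the origin of the first-mentioned causal sequence; (3)
#' Part-II promotion (AIDS/Kaposi pattern); (4) the neonatal remap for
#' deaths under 28 days; (5) the year-dependent rule remap; (6) the reject
#' predicate -- certificates needing the fallback while carrying at least
#' `reject_min_codes` codes are rejected as too complex instead of coded.
#'
#' The oracle is a pure function: identical `(cert, model)` always yield an
#' identical result.
#'
#' @param cert A `ucd_certificate` whose codes are all in `model$vocab`.
#' @param model A `ucd_cause_model`.
#' @param apply_reject Set `FALSE` to force a coded answer (the fallback
#'   label a human coder would complete a reject with).
#' @return Object of class `ucd_oracle_result`: list with `ucd` (code or
#'   `NA` when rejected), `rejected` flag, and `trace` of applied rules.
#' @export
oracle_code <- function(cert, model, apply_reject = TRUE) {
  stopifnot(inherits(cert, "ucd_certificate"),
            inherits(model, "ucd_cause_model"))
  sel <- oracle_select(cert, model)
  rejected <- apply_reject && oracle_reject(cert, model, sel$trace)
  structure(
    list(
      ucd = if (rejected) NA_character_ else sel$selected,
      rejected = rejected,
      trace = if (rejected) c(sel$trace, "reject") else sel$trace
    ),
    class = "ucd_oracle_result"
  )
}

#' @export
print.ucd_oracle_result <- function(x, ...) {
  if (x$rejected) cat("<oracle> REJECTED (", paste(x$trace, collapse = " > "), ")\n")
  else cat("<oracle> UCD =", x$ucd, "(", paste(x$trace, collapse = " > "), ")\n")
  invisible(x)
}

label_certificate <- function(cert, model) {
  sel <- oracle_select(cert, model)
  cert$gold_ucd <- sel$selected
  cert$rejected <- oracle_reject(cert, model, sel$trace)
  cert
}

#' Generate a labeled synthetic dataset
#'
#' Samples `n` certificates and labels each with the oracle. Rejected
#' certificates carry the reject flag *and* a gold label from the fallback
#' rule, mirroring a production corpus in which rejects are completed by
#' human coders. Byte-identical across runs for a fixed seed.
#'
#' @param model A `ucd_cause_model`.
#' @param n Number of certificates.
#' @param seed Integer seed.
#' @return List of labeled `ucd_certificate`.
#' @export
generate_dataset <- function(model, n, seed = 1L) {
  stopifnot(inherits(model, "ucd_cause_model"), n >= 1)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  lapply(seq_len(n), function(i) {
    label_certificate(sample_certificate(model, id = sprintf("SYN%06d", i)),
                      model)
  })
}

#' Generate a year-balanced labeled corpus
#'
#' Like [generate_dataset()] but with exactly `n_per_year` certificates for
#' each modelled calendar year, as needed by the stratified train/val/test
#' protocol and the harmonization experiment.
#'
#' @param model A `ucd_cause_model`.
#' @param n_per_year Certificates per calendar year.
#' @param seed Integer seed.
#' @return List of labeled `ucd_certificate`, ordered by year.
#' @export
generate_corpus <- function(model, n_per_year, seed = 1L) {
  stopifnot(inherits(model, "ucd_cause_model"), n_per_year >= 1)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  p <- model$params
  years <- seq(p$base_year, length.out = p$n_years)
  out <- vector("list", n_per_year * length(years))
  k <- 0L
  for (y in years) {
    for (i in seq_len(n_per_year)) {
      k <- k + 1L
      out[[k]] <- label_certificate(
        sample_certificate(model, demo = list(year = y),
                           id = sprintf("SYN%d_%05d", y, i)),
        model)
    }
  }
  out
}

#' Serialize / restore the generator configuration
#'
#' A cause model is fully determined by `(vocabulary parameters, generator
#' parameters, seeds)`; these are written to a small JSON file from which
#' [restore_cause_model()] rebuilds the identical model.
#'
#' @param model A `ucd_cause_model` built on a synthetic vocabulary.
#' @param vocab_spec List with `n_chapters`, `codes_per_chapter`, `seed`
#'   used to build the vocabulary.
#' @param path JSON file path.
#' @export
save_cause_model_config <- function(model, vocab_spec, path) {
  stopifnot(inherits(model, "ucd_cause_model"))
  cfg <- list(vocab = vocab_spec, seed = model$seed,
              params = model$params,
              vocab_fingerprint = vocab_fingerprint(model$vocab))
  jsonlite::write_json(cfg, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_cause_model_config
#' @param path JSON file written by [save_cause_model_config()].
#' @return The rebuilt `ucd_cause_model`.
#' @export
restore_cause_model <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  vocab <- make_synthetic_vocabulary(cfg$vocab$n_chapters,
                                     cfg$vocab$codes_per_chapter,
                                     cfg$vocab$seed)
  if (!identical(vocab_fingerprint(vocab), cfg$vocab_fingerprint)) {
    stop("restored vocabulary does not match the stored fingerprint")
  }
  make_cause_model(vocab, params = cfg$params, seed = cfg$seed)
}
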