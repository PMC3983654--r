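CONSEQ3 <- c("synonymous", "missense", "nonsense")

# lookup of (codon, position, alt) -> consequence, built once per session
codon_change_table <- local({
  tbl <- NULL
  function() {
    if (!is.null(tbl)) return(tbl)
    gc_ <- Biostrings::GENETIC_CODE
    codons <- names(gc_)
    rows <- list()
    for (codon in codons) {
      for (p in 1:3) {
        ref <- substr(codon, p, p)
        for (alt in setdiff(DNA_BASES, ref)) {
          mut <- codon
          substr(mut, p, p) <- alt
          aa_ref <- gc_[[codon]]
          aa_alt <- gc_[[mut]]
          cons <- if (aa_alt == "*" && aa_ref != "*") "nonsense"
            else if (aa_ref == aa_alt) "synonymous"
            else "missense"
          rows[[length(rows) + 1]] <- data.frame(
            codon = codon, pos = p, type = paste0(ref, ">", alt),
            consequence = cons, stringsAsFactors = FALSE
          )
        }
      }
    }
    tbl <<- do.call(rbind, rows)
    tbl
  }
})

#' Opportunity matrix of a set of coding sequences
#'
#' For each of the 12 strand-specific substitution types, counts the coding
#' positions at which that substitution would produce a synonymous,
#' missense or nonsense change (stop codons are not part of the input CDS;
#' an internal stop is an error). The matrix normalises selection estimates
#' for sequence composition: its entries sum to three times the total CDS
#' length.
#'
#' @param cds_sequences character vector (or DNAStringSet) of in-frame
#'   coding sequences, lengths divisible by three
#' @return 12 x 3 integer matrix (types x consequence classes)
#' @export
build_opportunity_matrix <- function(cds_sequences) {
  if (inherits(cds_sequences, "DNAStringSet")) {
    cds_sequences <- as.character(cds_sequences)
  }
  if (any(nchar(cds_sequences) %% 3 != 0)) {
    stop("CDS length must be divisible by 3")
  }
  codons <- unlist(lapply(cds_sequences, function(s) {
    substring(s, seq(1, nchar(s), 3), seq(3, nchar(s), 3))
  }))
  if (any(codons %in% STOP_CODONS)) {
    stop("internal stop codon in CDS input")
  }
  codon_counts <- table(codons)
  tbl <- codon_change_table()
  tbl <- tbl[tbl$codon %in% names(codon_counts), ]
  w <- as.numeric(codon_counts[tbl$codon])
  L <- matrix(0L, nrow = 12, ncol = 3,
              dimnames = list(SUBSTITUTION_TYPES, CONSEQ3))
  agg <- stats::aggregate(
    w, by = list(type = tbl$type, consequence = tbl$consequence), FUN = sum
  )
  for (i in seq_len(nrow(agg))) {
    L[agg$type[i], agg$consequence[i]] <- agg$x[i]
  }
  storage.mode(L) <- "integer"
  L
}

#' Tabulate observed mutations by substitution type and consequence
#'
#' @param catalog an annotated mutation catalog (SNVs with consequence in
#'   synonymous/missense/nonsense are counted; everything else is excluded
#'   from the CDS-only selection model)
#' @return 12 x 3 integer matrix aligned with [build_opportunity_matrix()].
#'   Types are taken on the coding strand of the mutated gene, so records
#'   need `gene_id` and the gene models to orient them.
#' @param models a [gene_models()] object
#' @export
selection_counts <- function(catalog, models) {
  keep <- catalog$class == "SNV" & catalog$consequence %in% CONSEQ3
  m <- catalog[keep, ]
  n <- matrix(0L, nrow = 12, ncol = 3,
              dimnames = list(SUBSTITUTION_TYPES, CONSEQ3))
  if (nrow(m) == 0) return(n)
  strand <- setNames(models$genes$strand, models$genes$gene_id)[m$gene_id]
  ref <- ifelse(strand == "-", unname(COMPLEMENT[m$ref]), m$ref)
  alt <- ifelse(strand == "-", unname(COMPLEMENT[m$alt]), m$alt)
  tab <- table(factor(paste0(ref, ">", alt), levels = SUBSTITUTION_TYPES),
               factor(m$consequence, levels = CONSEQ3))
  n + unclass(tab)
}

#' Simulate type-by-consequence mutation counts from the selection model
#'
#' Counts are Poisson with mean proportional to
#' `rate[type] * L[type, class] * omega[class]` (omega_syn = 1), scaled so
#' the expected total equals `n_total`.
#'
#' @param L opportunity matrix
#' @param omega_mis,omega_non generating selection parameters
#' @param rates 12 relative substitution rates (default all equal)
#' @param n_total expected total mutation count
#' @return 12 x 3 integer count matrix
#' @export
simulate_selection_counts <- function(L, omega_mis, omega_non,
                                      rates = rep(1, 12), n_total = 10000) {
  w <- c(1, omega_mis, omega_non)
  mu <- sweep(L * rates, 2, w, `*`)
  mu <- mu * n_total / sum(mu)
  n <- matrix(rpois(length(mu), mu), nrow = nrow(L),
              dimnames = dimnames(L))
  storage.mode(n) <- "integer"
  n
}

selection_loglik <- function(n, L, r, w) {
  mu <- sweep(L * r, 2, w, `*`)
  ok <- mu > 0
  if (any(n[!ok] > 0)) return(-Inf)
  sum(n[ok] * log(mu[ok]) - mu[ok]) - sum(mu[!ok])
}

# coordinate-ascent ML fit of the 12-rate + selection model under a Poisson
# likelihood; fixed entries of `fix_w` (named) are held at 1
fit_rates_omegas <- function(n, L, fix_w = character(), tol = 1e-10,
                             max_iter = 10000) {
  w <- c(synonymous = 1, missense = 1, nonsense = 1)
  free <- setdiff(c("missense", "nonsense"), fix_w)
  r <- rowSums(n) / pmax(rowSums(L), 1)
  ll_old <- -Inf
  for (iter in seq_len(max_iter)) {
    denom <- as.vector(L %*% w)
    r <- ifelse(denom > 0, rowSums(n) / denom, 0)
    for (cc in free) {
      d <- sum(r * L[, cc])
      w[cc] <- if (d > 0) sum(n[, cc]) / d else 0
    }
    ll <- selection_loglik(n, L, r, w)
    if (is.finite(ll) && ll - ll_old < tol && iter > 1) break
    ll_old <- ll
  }
  list(rates = r, w = w, loglik = ll)
}

#' Fit the mutation-selection (dN/dS) model
#'
#' Maximum-likelihood estimation of 12 substitution-rate parameters and two
#' selection parameters omega_mis (dM/dS) and omega_non (dNS/dS), with
#' omega_syn fixed at 1, under a Poisson likelihood over type x consequence
#' counts: `mu[s, c] = r[s] * L[s, c] * omega[c]`. Likelihood-ratio tests
#' against the neutral constraints omega_mis = 1 and omega_non = 1 use a
#' chi-squared reference with one degree of freedom each.
#'
#' Substitution types with zero total opportunity are excluded with a
#' warning (their rate is unidentifiable).
#'
#' @param n observed 12 x 3 count matrix (see [selection_counts()])
#' @param L opportunity matrix (see [build_opportunity_matrix()])
#' @param tol convergence tolerance on the log-likelihood
#' @return a `selection_fit` list: `rates`, `omega_mis`, `omega_non`,
#'   `loglik_full`, `loglik_null_mis`, `loglik_null_non`, `p_mis`, `p_non`
#' @export
fit_selection_model <- function(n, L, tol = 1e-10) {
  stopifnot(identical(dim(n), dim(L)))
  if (sum(n) < 1) stop("no observed mutations")
  zero_opp <- rowSums(L) == 0
  if (any(zero_opp)) {
    if (any(n[zero_opp, ] > 0)) {
      stop("observed mutations of a type with zero opportunity")
    }
    warning("excluding substitution type(s) with zero opportunity: ",
            paste(rownames(L)[zero_opp], collapse = ", "))
    n <- n[!zero_opp, , drop = FALSE]
    L <- L[!zero_opp, , drop = FALSE]
  }
  for (cc in CONSEQ3) {
    if (sum(n[, cc]) > 0 && sum(L[, cc]) == 0) {
      stop("mutations observed in class ", cc, " with zero opportunity")
    }
  }
  full <- fit_rates_omegas(n, L, tol = tol)
  null_mis <- fit_rates_omegas(n, L, fix_w = "missense", tol = tol)
  null_non <- fit_rates_omegas(n, L, fix_w = "nonsense", tol = tol)
  fit <- structure(list(
    rates = full$rates,
    omega_mis = unname(full$w["missense"]),
    omega_non = unname(full$w["nonsense"]),
    loglik_full = full$loglik,
    loglik_null_mis = null_mis$loglik,
    loglik_null_non = null_non$loglik
  ), class = "selection_fit")
  p <- lrt_neutrality(fit)
  fit$p_mis <- p[["p_mis"]]
  fit$p_non <- p[["p_non"]]
  fit
}

#' Likelihood-ratio tests of neutrality (omega = 1)
#'
#' The statistic is twice the log-likelihood gap between the full fit and
#' the constrained fit, referred to chi-squared with 1 df. Tiny negative
#' gaps from finite convergence are clamped to zero.
#'
#' @param fit a [fit_selection_model()] result
#' @return named vector `p_mis`, `p_non`
#' @export
lrt_neutrality <- function(fit) {
  stat <- function(ll0) {
    s <- 2 * (fit$loglik_full - ll0)
    if (s < 0 && s > -1e-6) s <- 0
    if (s < 0) stop("constrained fit exceeds full fit: non-nested models")
    s
  }
  c(p_mis = pchisq(stat(fit$loglik_null_mis), df = 1, lower.tail = FALSE),
    p_non = pchisq(stat(fit$loglik_null_non), df = 1, lower.tail = FALSE))
}

#' @export
print.selection_fit <- function(x, ...) {
  cat("mutation-selection fit: omega_mis =", signif(x$omega_mis, 4),
      "(p =", signif(x$p_mis, 3), "), omega_non =",
      signif(x$omega_non, 4), "(p =", signif(x$p_non, 3), ")\n")
  invisible(x)
}
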