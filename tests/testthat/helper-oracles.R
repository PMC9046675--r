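# Exact-fraction arithmetic on (numerator, denominator) pairs. Values stay
# exact as long as intermediates fit in a double's 2^53 integer range, which
# the small rational test instances guarantee.
frac <- function(num, den = 1) {
  stopifnot(den != 0)
  g <- frac_gcd(abs(num), abs(den))
  if (g > 0) { num <- num / g; den <- den / g }
  if (den < 0) { num <- -num; den <- -den }
  list(n = num, d = den)
}
frac_gcd <- function(a, b) if (b == 0) a else frac_gcd(b, a %% b)
f_add <- function(x, y) frac(x$n * y$d + y$n * x$d, x$d * y$d)
f_sub <- function(x, y) f_add(x, frac(-y$n, y$d))
f_mul <- function(x, y) frac(x$n * y$n, x$d * y$d)
f_div <- function(x, y) { stopifnot(y$n != 0); frac(x$n * y$d, x$d * y$n) }
f_num <- function(x) x$n / x$d
f_sum <- function(xs) Reduce(f_add, xs, frac(0))

# Exact-fraction fixed-effect + DerSimonian-Laird oracle. Weights w are
# integers (se = 1/sqrt(w)); thetas are fractions. Returns doubles computed
# from exact rationals (a single final division/sqrt each).
dl_oracle <- function(theta_fracs, weights) {
  k <- length(weights)
  w <- lapply(weights, frac)
  sw <- f_sum(w)
  th_fe <- f_div(f_sum(Map(f_mul, w, theta_fracs)), sw)
  Q <- f_sum(Map(function(wi, ti) f_mul(wi, f_mul(f_sub(ti, th_fe), f_sub(ti, th_fe))),
                 w, theta_fracs))
  C <- f_sub(sw, f_div(f_sum(Map(f_mul, w, w)), sw))
  tau2 <- f_div(f_sub(Q, frac(k - 1)), C)
  if (f_num(tau2) < 0) tau2 <- frac(0)
  wr <- lapply(w, function(wi) f_div(frac(1), f_add(f_div(frac(1), wi), tau2)))
  swr <- f_sum(wr)
  th_re <- f_div(f_sum(Map(f_mul, wr, theta_fracs)), swr)
  i2 <- if (f_num(Q) > 0) max(0, f_num(f_sub(Q, frac(k - 1))) / f_num(Q)) * 100 else 0
  list(theta_fe = f_num(th_fe), se_fe = 1 / sqrt(f_num(sw)),
       Q = f_num(Q), i2 = i2, tau2 = f_num(tau2),
       theta_re = f_num(th_re), se_re = 1 / sqrt(f_num(swr)))
}

# All permutations of 1..n (for brute-force rank-test nulls at tiny n)
all_perms <- function(n) {
  if (n == 1) return(matrix(1, 1, 1))
  sub <- all_perms(n - 1)
  do.call(rbind, lapply(seq_len(n), function(i) {
    rest <- setdiff(seq_len(n), i)
    cbind(i, matrix(rest[sub], nrow(sub)))
  }))
}

# Kendall S between two vectors
kendall_S <- function(x, y) {
  pr <- utils::combn(length(x), 2)
  sum(sign(x[pr[1, ]] - x[pr[2, ]]) * sign(y[pr[1, ]] - y[pr[2, ]]))
}

# A blank study-table row set with the full schema, for building fixtures in
# code; override columns via ...
make_studies <- function(n, ...) {
  cols <- study_table_columns()
  df <- tibble::as_tibble(setNames(rep(list(rep(NA_real_, n)), length(cols)), cols))
  df$study_id <- paste0("s", seq_len(n))
  df$pmid <- NA_character_
  df$year <- 2010L + seq_len(n)
  df$variant_id <- "rs0000001"
  df$effect_allele <- "C"
  df$other_allele <- "A"
  df$outcome_name <- "test outcome"
  df$outcome_kind <- "disease"
  df$design <- "case_control"
  df$ancestry <- "European"
  df$is_first_report <- c(TRUE, rep(FALSE, n - 1))
  over <- list(...)
  for (nm in names(over)) df[[nm]] <- over[[nm]]
  df
}
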