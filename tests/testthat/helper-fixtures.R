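# Small in-code fixtures shared across test files.

# minimal person table row
person_row <- function(id, sex = "M", birth = "2000-01-01", place = "BP001",
                       mother = "M1", father = "F1",
                       death = NA, emig = NA) {
  data.table::data.table(
    person_id = id, sex = sex, birth_date = as.Date(birth),
    birthplace = place, mother_id = mother, father_id = father,
    death_date = as.Date(death), emigration_date = as.Date(emig))
}

persons_table <- function(...) data.table::rbindlist(list(...))

# pair table with identical covariates, direct y patterns
toy_pair_table <- function(y_ss, y_ref, byear = 2000L) {
  n_ss <- nrow(y_ss); n_ref <- nrow(y_ref)
  data.table::data.table(
    pair_id = sprintf("p%04d", seq_len(n_ss + n_ref)),
    group = c(rep("SS", n_ss), rep("REF", n_ref)),
    y1 = c(y_ss[, 1], y_ref[, 1]), y2 = c(y_ss[, 2], y_ref[, 2]),
    sex1 = c(rep("M", n_ss), rep("M", n_ref)),
    sex2 = c(rep("M", n_ss), rep("F", n_ref)),
    byear1 = byear, byear2 = byear)
}

# gaussian outcome pair table generated directly under the variance-component
# model: u_pair shared in every pair, u_onlySS shared within SS pairs and
# independent per individual otherwise
sim_vc_pairs <- function(n_ss, n_ref, v_pair, v_only_ss, v_e,
                         beta_sex = 0, beta_byear = 0, seed = 1) {
  set.seed(seed)
  n <- n_ss + n_ref
  grp <- c(rep("SS", n_ss), rep("REF", n_ref))
  u_pair <- rnorm(n, sd = sqrt(v_pair))
  b_ss <- rnorm(n, sd = sqrt(v_only_ss))          # shared within SS pairs
  b1 <- ifelse(grp == "SS", b_ss, rnorm(n, sd = sqrt(v_only_ss)))
  b2 <- ifelse(grp == "SS", b_ss, rnorm(n, sd = sqrt(v_only_ss)))
  sex1 <- ifelse(grp == "SS", "M", sample(c("M", "F"), n, TRUE))
  sex2 <- ifelse(grp == "SS", sex1, sample(c("M", "F"), n, TRUE))
  byear1 <- sample(1980:2000, n, TRUE)
  byear2 <- sample(1980:2000, n, TRUE)
  y1 <- beta_sex * (sex1 == "M") + beta_byear * (byear1 - 1990) +
    u_pair + b1 + rnorm(n, sd = sqrt(v_e))
  y2 <- beta_sex * (sex2 == "M") + beta_byear * (byear2 - 1990) +
    u_pair + b2 + rnorm(n, sd = sqrt(v_e))
  data.table::data.table(
    pair_id = sprintf("p%05d", seq_len(n)), group = grp,
    y1 = y1, y2 = y2, sex1 = sex1, sex2 = sex2,
    byear1 = byear1, byear2 = byear2)
}

# binary pair table drawn from thresholded bivariate-normal liabilities with
# group-specific liability correlations (mixture already applied)
sim_threshold_pairs <- function(n_ss, n_ref, rho_ss, rho_ref, K, seed = 1) {
  set.seed(seed)
  draw <- function(n, rho) {
    z0 <- rnorm(n); z1 <- rnorm(n)
    l1 <- z0
    l2 <- rho * z0 + sqrt(1 - rho^2) * z1
    T <- qnorm(1 - K)
    cbind(as.integer(l1 > T), as.integer(l2 > T))
  }
  toy_pair_table(draw(n_ss, rho_ss), draw(n_ref, rho_ref))
}
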