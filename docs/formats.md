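# File formats

All text, all writes atomic (temp file + rename). Ids are 1-based in files
and in R.

## min.data

One local minimum per line, whitespace-separated, 6 columns:

```
<energy> <log_freq_product> <degeneracy_order> 1.0 1.0 1.0
```

Columns 4–6 are placeholders (moments-of-inertia slots in the wider
ecosystem format); written as `1.0`, ignored on read. Values are printed
with `%.17g`, so round-trips are exact. `log_freq_product` is the sum of the
logs of the positive normal-mode frequencies (0.5 * sum(log eigenvalues) in
unit-mass reduced units, constants dropped); `degeneracy_order` is a single
multiplicative permutation-inversion weight.

## ts.data

One transition state per line, 8 columns:

```
<energy> <log_freq_product> <degeneracy_order> <min1> <min2> 1.0 1.0 1.0
```

`min1`/`min2` are 1-based minimum ids (a 0 id is rejected). Dangling ids are
rejected when the database is assembled.

## Database directory

`write_database()`/`read_database()` use a directory containing `min.data`,
`ts.data`, optionally `points.xyz` (one XYZ frame per minimum, same order)
and `manifest.json` (metadata: at least `kappa`, the shared vibrational
degree-of-freedom count, plus generator design truth for synthetic
databases).

## XYZ

Standard multi-frame XYZ: atom-count line, comment line, then
`element x y z` per atom. 2D configurations are written with z = 0.

## Curves, features, trees

* `cv.csv`: columns `kbt, cv, mean_energy` (CV in units of kB, including
  the kappa baseline).
* `features.json`: `{"features": {"summary": [{kind, kbt, cv}...],
  "positive_sets": [...], "negative_sets": [...]}, "first_feature_kbt": x}`;
  each set is a table of `{id, dpdT}`.
* `contributions.csv`: columns `feature, sign, id, dpdT`.
* `tree.json`: `{e_top, delta_e, n_minima, root, leaf_colours}` where
  `root` is a recursive `{type: "node", energy, children: [...]}` /
  `{type: "leaf", min_id, energy}` structure.
* `descriptors.csv`: columns `id, energy, rel_energy, end_to_end, dihedral,
  contributes, class`.

## Config files

`--config` accepts YAML or JSON maps of long-option names to values
(e.g. `n-funnels: 2`); explicit command-line flags take precedence.

## CSV dialect

Comma-separated, header row, `.` decimal point, no locale handling.
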