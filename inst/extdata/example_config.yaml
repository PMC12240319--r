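# Example run configuration for the statindili pipeline.
# Either point input_dir at a directory of FAERS-style quarterly files
# (DEMO*.txt, DRUG*.txt, REAC*.txt, OUTC*.txt, THER*.txt) or supply a
# `synthetic` block to generate a database with planted structure.
synthetic:
  seed: 1
  n_cases: 20000
ic_ci_method: noren   # or "gamma"
stratify: true
out_dir: results
seed: 1
# smq_path: /path/to/official_smq_20000007_narrow.txt
# dict_path: /path/to/custom_statin_dictionary.csv
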