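# bmpassembly run configuration (see ?read_run_config)
# Affinity / enumeration convention
het_typeii: shared        # shared | per-face (heterodimer type-II K_D rule)
acvr1_bmp2: yes           # allow Acvr1 on Bmp2 faces
acvr1_bmp2_kd: 1024.0     # nM
merge_sites: class        # class | symmetry | none
site_kinetics: microstate # microstate | ordered
kon_ref: 1.0e-3           # /nM/s reference association rate
# Screen grid (values in nM; gamma dimensionless)
ligand: [0.01, 0.0316227766016838, 0.1, 0.316227766016838, 1.0]
bmpr1: [1.0, 4.5, 8.0, 11.5, 15.0, 18.5, 22.0, 25.5, 29.0, 32.5, 36.0, 39.5, 43.0, 46.5, 50.0]
acvr1: [1.0, 4.5, 8.0, 11.5, 15.0, 18.5, 22.0, 25.5, 29.0, 32.5, 36.0, 39.5, 43.0, 46.5, 50.0]
typeii: [1.0, 4.5, 8.0, 11.5, 15.0, 18.5, 22.0, 25.5, 29.0, 32.5, 36.0, 39.5, 43.0, 46.5, 50.0]
gamma: [10.0, 50.0, 100.0, 500.0, 1000.0]
seed: 1
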