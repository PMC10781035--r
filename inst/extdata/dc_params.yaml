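# Dang-Chang rigid polarizable 4-site water model.
# Parameter provenance: L. X. Dang and T.-M. Chang,
# J. Chem. Phys. 106, 8149 (1997).
# Units: kcal/mol (epsilon), Angstrom (sigma, lengths), electron charges
# (q_h, q_m), Angstrom^3 (alpha), degrees (theta_hoh).
epsilon: 0.1825        # LJ well depth, O-O
sigma: 3.234           # LJ diameter, O-O
q_h: 0.519             # hydrogen partial charge
q_m: -1.038            # M-site partial charge (-2 q_h)
alpha: 1.444           # isotropic polarizability on the M site
coulomb_k: 332.0637    # kcal mol^-1 A e^-2
cutoff: 20.0           # polarization O-O cutoff radius, Angstrom
mutual: true           # mutual dipole-dipole induction in the SCF
scf_tol: 1.0e-10
scf_maxit: 2000
overlap_floor: 0.1     # hard O-O floor, Angstrom
geom:
  r_oh: 0.9572         # O-H bond length
  theta_hoh: 104.5     # H-O-H angle
  r_om: 0.215          # O-M distance along the bisector
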