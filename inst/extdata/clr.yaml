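# Example per-time-delay configuration for a chloride-pumping rhodopsin
# TR-SFX study (dark state + 1 ps delay).  Point the model paths at your
# local copies of the deposited entries (7CRJ = dark, 7CRI = 1 ps,
# 7CRK = 2 ps, 7CRS = 50/100 ps companions) and the amplitude files at
# your merged data; residue numbers below follow the deposited entries
# and may need adjusting for other numbering schemes.
dark_model: 7CRJ.pdb
light_model: 7CRI.pdb
dark_obs: dark_obs.tsv
pump_obs: pump_obs_1ps.tsv
d_min: 1.85
alpha: 1.0
# the extrapolation-factor criterion follows the vacated density around
# the isomerizing retinal carbons and the displaced chloride
mask_atoms:
  - resname RLY and name C13,C14
  - element CL and resno 301
mask_radius: 2.0
peak_threshold: 3.5
out_dir: out_1ps
measurements:
  - name: retinal_C12_C13_C14_C15_torsion
    type: torsion
    atoms:
      - resname RLY and name C12
      - resname RLY and name C13
      - resname RLY and name C14
      - resname RLY and name C15
  - name: retinal_C14_C15_NZ_CE_torsion
    type: torsion
    atoms:
      - resname RLY and name C14
      - resname RLY and name C15
      - resname RLY and name NZ
      - resname RLY and name CE
  - name: Thr102_OG1_to_Cl1
    type: distance
    atoms:
      - resno 102 and name OG1
      - element CL and resno 301
  - name: Asn98_ND2_to_Cl1
    type: distance
    atoms:
      - resno 98 and name ND2
      - element CL and resno 301
  - name: Cl1_displacement
    type: displacement
    a: element CL and resno 301
  - name: Lys235_CA_displacement
    type: displacement
    a: resno 235 and name CA
  - name: NZ_to_ionone_centroid
    type: centroid_distance
    a: resname RLY and name NZ
    ring: resname RLY and name C1,C2,C3,C4,C5,C6
  - name: retinal_lysine_rmsd
    type: rmsd
    selection: resname RLY
  - name: Trp99_indole_rotation
    type: plane_rotation
    selection: resno 99 and name CG,CD1,CD2,NE1,CE2,CE3,CZ2,CZ3,CH2
  - name: TMG_kink_about_Lys235
    type: helix_kink
    segment1: resi 225-234 and name CA
    segment2: resi 236-245 and name CA
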