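data_TOY1
_entry.id TOY1
_refine.ls_d_res_high 1.20
_refine.ls_R_factor_R_work 0.150
loop_
_atom_site.group_PDB
_atom_site.id
_atom_site.type_symbol
_atom_site.label_atom_id
_atom_site.label_alt_id
_atom_site.label_comp_id
_atom_site.label_asym_id
_atom_site.label_entity_id
_atom_site.label_seq_id
_atom_site.pdbx_PDB_ins_code
_atom_site.Cartn_x
_atom_site.Cartn_y
_atom_site.Cartn_z
_atom_site.occupancy
_atom_site.B_iso_or_equiv
_atom_site.pdbx_formal_charge
_atom_site.auth_seq_id
_atom_site.auth_comp_id
_atom_site.auth_asym_id
_atom_site.auth_atom_id
_atom_site.pdbx_PDB_model_num
ATOM 1 N N . ALA A 1 1 ? 0.000 0.000 0.000 1.00 20.00 ? 1 ALA A N 1
ATOM 2 C CA . ALA A 1 1 ? 1.458 0.000 0.000 1.00 20.00 ? 1 ALA A CA 1
ATOM 3 C C . ALA A 1 1 ? 2.005 1.424 0.000 1.00 20.00 ? 1 ALA A C 1
ATOM 4 O O . ALA A 1 1 ? 1.365 2.330 -0.534 1.00 20.00 ? 1 ALA A O 1
ATOM 5 N N . ALA A 1 2 ? 3.158 1.632 0.626 1.00 20.00 ? 2 ALA A N 1
ATOM 6 C CA . ALA A 1 2 ? 3.791 2.945 0.650 1.00 20.00 ? 2 ALA A CA 1
ATOM 7 C C . ALA A 1 2 ? 4.171 3.394 -0.756 1.00 20.00 ? 2 ALA A C 1
ATOM 8 O O . ALA A 1 2 ? 4.462 2.559 -1.613 1.00 20.00 ? 2 ALA A O 1
ATOM 9 N N . ALA A 1 3 ? 4.132 4.698 -1.009 1.00 20.00 ? 3 ALA A N 1
ATOM 10 C CA . ALA A 1 3 ? 4.517 5.239 -2.307 1.00 20.00 ? 3 ALA A CA 1
ATOM 11 C C . ALA A 1 3 ? 5.987 4.959 -2.602 1.00 20.00 ? 3 ALA A C 1
ATOM 12 O O . ALA A 1 3 ? 6.803 4.910 -1.681 1.00 20.00 ? 3 ALA A O 1
#
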