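category	item	required	domain	key	parent	origin
sas_scan	id	1	number	1		dictionary
sas_scan	title	0	text	0		dictionary
sas_scan	unit	0	enum:1/angstrom|1/nm	0		dictionary
sas_scan	storage_temperature	0	number	0		dictionary
sas_scan	cell_temperature	0	number	0		dictionary
sas_scan	number_of_frames	0	number	0		dictionary
sas_scan	momentum_transfer_min	0	number	0		dictionary
sas_scan	momentum_transfer_max	0	number	0		dictionary
sas_scan_intensity	id	1	number	1	sas_scan.id	dictionary
sas_scan_intensity	momentum_transfer	1	number	0		dictionary
sas_scan_intensity	intensity	1	number	0		dictionary
sas_scan_intensity	error	0	number	0		dictionary
sas_sample	id	1	number	1		dictionary
sas_sample	name	0	text	0		dictionary
sas_sample	specimen_concentration	0	number	0		dictionary
sas_sample	extinction_coefficient	0	number	0		local
sas_sample	partial_specific_volume	0	number	0		local
sas_sample	molecular_mass	0	number	0		local
sas_sample	contrast	0	number	0		local
sas_sample	deuteration_level	0	number	0		local
sas_sample	entity_id	0	number	0	entity.id	dictionary
sas_buffer	id	1	number	1		dictionary
sas_buffer	composition	0	text	0		dictionary
sas_buffer	ph	0	number	0		dictionary
sas_beam	id	1	number	1		dictionary
sas_beam	name	0	text	0		dictionary
sas_beam	location	0	text	0		dictionary
sas_beam	source_type	0	enum:x-ray|neutron	0		dictionary
sas_beam	radiation_wavelength	0	number	0		local
sas_detc	id	1	number	1		dictionary
sas_detc	name	0	text	0		dictionary
sas_detc	type	0	text	0		dictionary
sas_result	id	1	number	1		dictionary
sas_result	rg_from_guinier	0	number	0		dictionary
sas_result	rg_from_guinier_error	0	number	0		dictionary
sas_result	i0_from_guinier	0	number	0		dictionary
sas_result	rg_from_pr	0	number	0		dictionary
sas_result	rg_from_pr_error	0	number	0		dictionary
sas_result	i0_from_pr	0	number	0		dictionary
sas_result	dmax	0	number	0		dictionary
sas_result	mw_from_i0	0	number	0		dictionary
sas_result	mw_from_porod_volume	0	number	0		dictionary
sas_result	mw_from_ab_initio_volume	0	number	0		dictionary
sas_result	porod_volume	0	number	0		dictionary
sas_p_of_r_details	id	1	number	1		dictionary
sas_p_of_r_details	dmax	0	number	0		dictionary
sas_p_of_r_details	rg	0	number	0		dictionary
sas_p_of_r_details	i0	0	number	0		dictionary
sas_p_of_r_details	software	0	text	0		local
sas_p_of_r	id	1	number	1		dictionary
sas_p_of_r	r	1	number	0		dictionary
sas_p_of_r	p	1	number	0		dictionary
sas_p_of_r	p_error	0	number	0		dictionary
sas_p_of_r_extrapolated_intensity	id	1	number	1		dictionary
sas_p_of_r_extrapolated_intensity	momentum_transfer	1	number	0		dictionary
sas_p_of_r_extrapolated_intensity	intensity_reg	0	number	0		dictionary
sas_p_of_r_extrapolated_intensity	intensity_ext	0	number	0		dictionary
sas_model	id	1	number	1		dictionary
sas_model	type	0	enum:ab-initio|rigid-body|atomic	0		dictionary
sas_model	symmetry	0	text	0		dictionary
sas_model	bead_radius	0	number	0		dictionary
sas_model	software	0	text	0		dictionary
sas_model_fitting_details	id	1	number	1		dictionary
sas_model_fitting_details	model_id	1	number	0	sas_model.id	dictionary
sas_model_fitting_details	chi_square	0	number	0		dictionary
sas_model_fitting_details	p_value	0	number	0		dictionary
sas_model_fitting_details	software	0	text	0		local
sas_model_fitting	id	1	number	1		dictionary
sas_model_fitting	momentum_transfer	1	number	0		dictionary
sas_model_fitting	intensity	0	number	0		dictionary
sas_model_fitting	fitted_intensity	0	number	0		dictionary
atom_site	group_pdb	0	text	0		dictionary
atom_site	id	1	number	1		dictionary
atom_site	label_atom_id	0	text	0		dictionary
atom_site	label_comp_id	0	text	0		dictionary
atom_site	auth_asym_id	0	text	0		dictionary
atom_site	auth_seq_id	0	number	0		dictionary
atom_site	cartn_x	1	number	0		dictionary
atom_site	cartn_y	1	number	0		dictionary
atom_site	cartn_z	1	number	0		dictionary
atom_site	occupancy	0	number	0		dictionary
atom_site	b_iso_or_equiv	0	number	0		dictionary
atom_site	type_symbol	0	text	0		dictionary
entity	id	1	number	1		dictionary
entity	type	0	text	0		dictionary
entity	pdbx_description	0	text	0		dictionary
citation	id	1	text	1		dictionary
citation	title	0	text	0		dictionary
citation	journal_abbrev	0	text	0		dictionary
citation	journal_volume	0	text	0		dictionary
citation	page_first	0	text	0		dictionary
citation	page_last	0	text	0		dictionary
citation	year	0	number	0		dictionary
citation	pdbx_database_id_pubmed	0	text	0		dictionary
citation_author	citation_id	1	text	0	citation.id	dictionary
citation_author	name	1	text	0		dictionary
citation_author	ordinal	1	number	1		dictionary
struct_ref	id	1	number	1		dictionary
struct_ref	db_name	0	text	0		dictionary
struct_ref	db_code	0	text	0		dictionary
struct_ref	entity_id	0	number	0	entity.id	dictionary
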