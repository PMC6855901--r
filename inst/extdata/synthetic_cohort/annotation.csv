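metabolite_id,display_name,platform,super_pathway,sub_pathway
M0001,M0001,polar,super_3,pathway_03
M0002,M0002,pos_late,super_4,pathway_04
M0003,M0003,pos_early,super_1,pathway_01
M0004,M0004,polar,super_4,pathway_04
M0005,M0005,polar,super_3,pathway_03
M0006,M0006,neg,super_1,pathway_01
M0007,M0007,neg,super_4,pathway_04
M0008,M0008,neg,super_4,pathway_04
M0009,M0009,polar,super_1,pathway_01
M0010,M0010,neg,super_2,pathway_02
M0011,M0011,neg,super_1,pathway_01
M0012,M0012,pos_early,super_1,pathway_01
M0013,M0013,polar,super_2,pathway_02
M0014,M0014,polar,super_4,pathway_04
M0015,M0015,polar,super_2,pathway_02
M0016,M0016,neg,super_2,pathway_02
M0017,M0017,polar,super_2,pathway_02
M0018,M0018,pos_early,super_1,pathway_01
M0019,M0019,pos_late,super_4,pathway_04
M0020,M0020,pos_late,super_3,pathway_03
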