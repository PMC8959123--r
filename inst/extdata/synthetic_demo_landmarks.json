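{"image_id":"synthetic_demo","pixel_spacing_mm":0.2,"hips":{"left":{"E":[800.716007911784,384.634821149555],"Y":[766.726256822675,401.265725209922],"C":[785.881381480142,419.160863814063],"H":[788.095888828738,444.18379476942]},"right":{"E":[540.03599190318,381.848239180043],"Y":[568.609739308447,404.573290785402],"C":[513.231654707764,405.06574031921],"H":[515.742733437201,431.895218648985]}},"head_rois":[{"side":"left","bbox":[765.07284483386,399.373112846246,805.07284483386,439.373112846246],"mask_area":1256.63706143592,"confidence":1},{"side":"right","bbox":[496.009376109988,385.623317852845,536.009376109988,425.623317852845],"mask_area":1256.63706143592,"confidence":1}],"contours":{"left":{"pubic_arc":[[751.828840438122,399.52618455923],[748.332024348334,401.311397107408],[744.971473350197,403.34152114226],[741.764312041288,405.60621161705],[738.726883380492,408.093928188234],[735.874665408023,410.791994022399],[733.222192372881,413.686660394506],[730.782980669652,416.763176748241],[728.569459962059,420.005865861465],[726.592909844243,423.398203733749],[724.863402362539,426.922903788888],[723.389750690635,430.562004963334]],"neck_arc":[[813.96371779912,410.482239880986],[810.833022767955,407.585439135906],[807.487261818994,404.939954377442],[803.946556752261,402.561695862211],[800.232201784642,400.46496671676],[796.36653548396,398.662376916881],[792.372806422199,397.164767449729],[788.275033355855,395.981145114857],[784.097860774313,395.118628356256],[779.866410684981,394.5824044512]]},"right":{"pubic_arc":[[574.253380505727,397.776389565829],[577.750196595514,399.561602114006],[581.110747593652,401.591726148858],[584.31790890256,403.856416623649],[587.355337563356,406.344133194832],[590.207555535826,409.042199028997],[592.860028570968,411.936865401105],[595.299240274197,415.013381754839],[597.51276098179,418.256070868064],[599.489311099606,421.648408740347],[601.218818581309,425.173108795486],[602.692470253213,428.812209969933]],"neck_arc":[[487.118503144728,396.732444887585],[490.249198175893,393.835644142504],[493.594959124855,391.190159384041],[497.135664191588,388.81190086881],[500.850019159207,386.715171723359],[504.715685459888,384.912581923479],[508.70941452165,383.414972456328],[512.807187587993,382.231350121456],[516.984360169536,381.368833362855],[521.215810258867,380.832609457799]]}}}
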