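<?xml version="1.0" encoding="UTF-8"?>
<!-- Schema for adverse-event report batches produced by export_xml().
     Field list and order mirror the four-screen reporting form; the
     regulator's own electronic-submission element list is not reproduced
     here, so this is the package's documented dialect. -->
<xs:schema xmlns:xs="http://www.w3.org/2001/XMLSchema"
           elementFormDefault="unqualified">

  <xs:simpleType name="speciesType">
    <xs:restriction base="xs:string">
      <xs:enumeration value="DOG"/>
      <xs:enumeration value="CAT"/>
      <xs:enumeration value="RABBIT"/>
      <xs:enumeration value="OTHER"/>
      <xs:enumeration value="HUMAN_FLAGGED"/>
      <xs:enumeration value="UNKNOWN"/>
    </xs:restriction>
  </xs:simpleType>

  <xs:simpleType name="sexType">
    <xs:restriction base="xs:string">
      <xs:enumeration value="MALE"/>
      <xs:enumeration value="FEMALE"/>
      <xs:enumeration value="UNKNOWN"/>
    </xs:restriction>
  </xs:simpleType>

  <xs:simpleType name="neuterType">
    <xs:restriction base="xs:string">
      <xs:enumeration value="NEUTERED"/>
      <xs:enumeration value="ENTIRE"/>
      <xs:enumeration value="UNKNOWN"/>
    </xs:restriction>
  </xs:simpleType>

  <xs:simpleType name="durationUnitType">
    <xs:restriction base="xs:string">
      <xs:enumeration value="HOURS"/>
      <xs:enumeration value="DAYS"/>
      <xs:enumeration value="WEEKS"/>
      <xs:enumeration value="MONTHS"/>
    </xs:restriction>
  </xs:simpleType>

  <xs:simpleType name="administratorType">
    <xs:restriction base="xs:string">
      <xs:enumeration value="VET"/>
      <xs:enumeration value="VET_NURSE"/>
      <xs:enumeration value="OWNER"/>
      <xs:enumeration value="OTHER"/>
      <xs:enumeration value="UNKNOWN"/>
    </xs:restriction>
  </xs:simpleType>

  <xs:simpleType name="yesNoType">
    <xs:restriction base="xs:string">
      <xs:enumeration value="YES"/>
      <xs:enumeration value="NO"/>
    </xs:restriction>
  </xs:simpleType>

  <xs:simpleType name="windowTagType">
    <xs:restriction base="xs:string">
      <xs:enumeration value="CURRENT_CONSULT"/>
      <xs:enumeration value="PRIOR_TWO_MONTHS"/>
    </xs:restriction>
  </xs:simpleType>

  <xs:complexType name="drugType">
    <xs:sequence>
      <xs:element name="product_name" type="xs:string"/>
      <xs:element name="marketing_auth_number" type="xs:string" minOccurs="0"/>
      <xs:element name="batch_number" type="xs:string" minOccurs="0"/>
      <xs:element name="route" type="xs:string" minOccurs="0"/>
      <xs:element name="start_date" type="xs:date" minOccurs="0"/>
      <xs:element name="admin_duration" type="xs:decimal" minOccurs="0"/>
      <xs:element name="admin_duration_unit" type="durationUnitType" minOccurs="0"/>
      <xs:element name="dosage_text" type="xs:string" minOccurs="0"/>
      <xs:element name="administrator" type="administratorType"/>
      <xs:element name="is_vaccine_or_pipette" type="xs:boolean"/>
    </xs:sequence>
  </xs:complexType>

  <xs:complexType name="noteType">
    <xs:simpleContent>
      <xs:extension base="xs:string">
        <xs:attribute name="note_date" type="xs:date" use="required"/>
        <xs:attribute name="window_tag" type="windowTagType" use="required"/>
      </xs:extension>
    </xs:simpleContent>
  </xs:complexType>

  <xs:complexType name="reportType">
    <xs:sequence>
      <xs:element name="report_id" type="xs:string"/>
      <xs:element name="practice_id" type="xs:string" minOccurs="0"/>
      <xs:element name="species" type="speciesType"/>
      <xs:element name="breed" type="xs:string" minOccurs="0"/>
      <xs:element name="date_of_birth" type="xs:date" minOccurs="0"/>
      <xs:element name="age_years" type="xs:nonNegativeInteger" minOccurs="0"/>
      <xs:element name="age_months" type="xs:nonNegativeInteger" minOccurs="0"/>
      <xs:element name="sex" type="sexType"/>
      <xs:element name="neuter_status" type="neuterType"/>
      <xs:element name="weight" type="xs:decimal" minOccurs="0"/>
      <xs:element name="suspect_drugs">
        <xs:complexType>
          <xs:sequence>
            <xs:element name="drug" type="drugType" maxOccurs="unbounded"/>
          </xs:sequence>
        </xs:complexType>
      </xs:element>
      <xs:element name="concurrent_products">
        <xs:complexType>
          <xs:sequence>
            <xs:element name="product" type="xs:string" minOccurs="0"
                        maxOccurs="unbounded"/>
          </xs:sequence>
        </xs:complexType>
      </xs:element>
      <xs:element name="reaction_date" type="xs:date" minOccurs="0"/>
      <xs:element name="reaction_duration" type="xs:decimal" minOccurs="0"/>
      <xs:element name="reaction_duration_unit" type="durationUnitType"
                  minOccurs="0"/>
      <xs:element name="fatal" type="yesNoType" minOccurs="0"/>
      <xs:element name="other_animals_text" type="xs:string" minOccurs="0"/>
      <xs:element name="reaction_description" type="xs:string"/>
      <xs:element name="clinical_notes">
        <xs:complexType>
          <xs:sequence>
            <xs:element name="note" type="noteType" minOccurs="0"
                        maxOccurs="unbounded"/>
          </xs:sequence>
        </xs:complexType>
      </xs:element>
      <xs:element name="submitted_to_manufacturer" type="yesNoType"/>
      <xs:element name="practice_postcode_area" type="xs:string" minOccurs="0"/>
      <xs:element name="reporter_name" type="xs:string" minOccurs="0"/>
      <xs:element name="reporter_email" type="xs:string" minOccurs="0"/>
      <xs:element name="reporter_phone" type="xs:string" minOccurs="0"/>
      <xs:element name="wants_copy" type="yesNoType"/>
      <xs:element name="submission_timestamp" type="xs:dateTime" minOccurs="0"/>
    </xs:sequence>
    <xs:attribute name="reference" type="xs:string" use="required"/>
  </xs:complexType>

  <xs:element name="ae_batch">
    <xs:complexType>
      <xs:sequence>
        <xs:element name="report" type="reportType" maxOccurs="unbounded"/>
      </xs:sequence>
      <xs:attribute name="batch_id" type="xs:string" use="required"/>
      <xs:attribute name="created_at" type="xs:dateTime" use="required"/>
    </xs:complexType>
  </xs:element>

</xs:schema>
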